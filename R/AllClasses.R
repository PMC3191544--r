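#' @import methods
#' @importFrom stats cor pchisq pt qt rnorm runif rbinom sd t.test var setNames median as.dist
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Position-specific scoring matrix for WRKY domain search
#'
#' A log-odds profile (bits) built from an aligned block of WRKY domain
#' sequences, used by the iterative family search in place of a full HMM.
#'
#' @slot length integer, number of profile columns.
#' @slot logOdds 20 x length numeric matrix of log2 odds scores, rows named
#'   by the 20 standard amino acids.
#' @slot background named numeric vector of 20 background frequencies,
#'   all positive, summing to 1.
#' @slot pseudocount positive numeric pseudocount weight.
#' @slot scoreThreshold numeric score (bits) above which a window is called
#'   a family member.
#' @exportClass PSSM
setClass("PSSM", representation(
  length = "integer",
  logOdds = "matrix",
  background = "numeric",
  pseudocount = "numeric",
  scoreThreshold = "numeric"
))

setValidity("PSSM", function(object) {
  msg <- character()
  if (ncol(object@logOdds) != object@length)
    msg <- c(msg, "logOdds column count must equal profile length")
  if (nrow(object@logOdds) != 20L ||
      !identical(rownames(object@logOdds), AA20))
    msg <- c(msg, "logOdds must have 20 rows named by the standard amino acids")
  if (any(!is.finite(object@logOdds)))
    msg <- c(msg, "logOdds entries must be finite")
  if (length(object@background) != 20L || any(object@background <= 0))
    msg <- c(msg, "background must have 20 strictly positive entries")
  if (abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background frequencies must sum to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single positive number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSSM", function(object) {
  cat("PSSM of length", object@length,
      "| pseudocount", object@pseudocount,
      "| score threshold", format(object@scoreThreshold, digits = 4),
      "bits\n")
  cat("max attainable score:",
      format(maxPssmScore(object), digits = 4), "bits\n")
})

#' Result of scanning a proteome for WRKY domains
#'
#' Container returned by [scanProteome()]: the input proteome, one row per
#' detected WRKY domain, and one group call per protein.
#'
#' @slot proteome an [Biostrings::AAStringSet] of the scanned proteins.
#' @slot domains data.frame of detected domains (see [domainTable()]).
#' @slot groups data.frame of group calls (see [groupCalls()]).
#' @exportClass WrkyScanResult
setClass("WrkyScanResult", representation(
  proteome = "AAStringSet",
  domains = "data.frame",
  groups = "data.frame"
))

setValidity("WrkyScanResult", function(object) {
  msg <- character()
  need <- c("protein_id", "sig_start", "domain_start", "domain_end",
            "signature_seq", "zf_type", "zf_gap1", "zf_gap2", "zf_gap3",
            "terminal_tag")
  if (!all(need %in% names(object@domains)))
    msg <- c(msg, "domains is missing required columns")
  if (!all(c("protein_id", "group", "n_domains", "evidence") %in%
           names(object@groups)))
    msg <- c(msg, "groups is missing required columns")
  if (anyDuplicated(names(object@proteome)))
    msg <- c(msg, "proteome ids must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WrkyScanResult", function(object) {
  cat("WrkyScanResult:", length(object@proteome), "proteins scanned,",
      nrow(object@domains), "WRKY domains in",
      sum(object@groups$n_domains > 0), "proteins\n")
  tab <- table(object@groups$group)
  tab <- tab[tab > 0]
  cat("group census:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})

#' Accessors for WrkyScanResult
#'
#' @param x a [WrkyScanResult-class] object.
#' @return `domainTable()` returns the per-domain data.frame with columns
#'   `protein_id`, `sig_start`, `domain_start`, `domain_end` (0-based
#'   half-open), `signature_seq`, `zf_type`, `zf_gap1..3`, `terminal_tag`;
#'   `groupCalls()` the per-protein data.frame with `protein_id`, `group`,
#'   `n_domains`, `evidence`; `proteome()` the scanned `AAStringSet`.
#' @export
domainTable <- function(x) {
  stopifnot(is(x, "WrkyScanResult"))
  x@domains
}

#' @rdname domainTable
#' @export
groupCalls <- function(x) {
  stopifnot(is(x, "WrkyScanResult"))
  x@groups
}

#' @rdname domainTable
#' @export
proteome <- function(x) {
  stopifnot(is(x, "WrkyScanResult"))
  x@proteome
}
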