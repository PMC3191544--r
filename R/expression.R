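# qPCR delta-delta-Ct quantification, differential-expression calls and
# summaries of the packaged family census tables.

STRESSES <- c("cold", "salt", "dry")
TIMEPOINTS_H <- c(0, 0.5, 1, 3, 6, 12, 24)

#' Relative expression by the delta-delta-Ct method
#'
#' Per replicate, delta-Ct = Ct(target) - Ct(reference) at matching
#' (stress, time, replicate); delta-delta-Ct subtracts the same
#' replicate's 0 h delta-Ct of the same stress; relative amount is
#' 2^-ddCt, averaged over replicates with its standard error. At 0 h the
#' relative amount is exactly 1 by construction.
#'
#' @param ct data.frame with columns `gene`, `stress`, `time_h`,
#'   `replicate`, `ct`, `is_reference` (logical). All Ct values must be
#'   positive; the reference gene must be measured at every
#'   (stress, time, replicate) where a target is measured.
#' @param reference_gene id of the reference gene (default: the gene
#'   flagged `is_reference`).
#' @return data.frame with one row per (gene, stress, time_h):
#'   `delta_ct` (replicate mean), `ddct` (replicate mean), `rel_amount`
#'   (mean of per-replicate 2^-ddct), `se`, `n_rep`, plus a
#'   `replicate_ddct` list-column used by [callDifferential()].
#' @export
relativeExpression <- function(ct, reference_gene = NULL) {
  need <- c("gene", "stress", "time_h", "replicate", "ct", "is_reference")
  stopifnot(all(need %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (is.null(reference_gene)) {
    reference_gene <- unique(ct$gene[ct$is_reference])
    if (length(reference_gene) != 1L)
      stop("need exactly one reference gene")
  }
  ref <- ct[ct$gene == reference_gene, ]
  ref_key <- paste(ref$stress, ref$time_h, ref$replicate)
  targets <- ct[ct$gene != reference_gene, ]
  key <- paste(targets$stress, targets$time_h, targets$replicate)
  miss <- !(key %in% ref_key)
  if (any(miss))
    stop("missing reference measurement at (stress, time): ",
         paste(unique(paste0("(", targets$stress[miss], ", ",
                             targets$time_h[miss], " h)")),
               collapse = ", "))
  targets$delta_ct <- targets$ct - ref$ct[match(key, ref_key)]
  out <- list()
  for (g in unique(targets$gene)) for (s in unique(targets$stress)) {
    sub <- targets[targets$gene == g & targets$stress == s, ]
    if (nrow(sub) == 0L) next
    base <- sub[sub$time_h == 0, ]
    if (nrow(base) == 0L)
      stop("no 0 h measurement for ", g, " under ", s)
    for (t in sort(unique(sub$time_h))) {
      st <- sub[sub$time_h == t, ]
      st <- st[order(st$replicate), ]
      ddct <- st$delta_ct -
        base$delta_ct[match(st$replicate, base$replicate)]
      if (any(is.na(ddct)))
        stop("replicate mismatch with 0 h sample for ", g, " under ", s)
      rel <- 2^(-ddct)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, stress = s, time_h = t,
        delta_ct = mean(st$delta_ct),
        ddct = mean(ddct),
        rel_amount = mean(rel),
        se = if (length(rel) > 1L) sd(rel) / sqrt(length(rel)) else NA_real_,
        n_rep = length(rel),
        stringsAsFactors = FALSE)
      out[[length(out)]]$replicate_ddct <- I(list(ddct))
      out[[length(out)]]$replicate_delta_ct <- I(list(st$delta_ct))
    }
  }
  do.call(rbind, out)
}

#' Differential-expression calls per gene and stress
#'
#' Per stress, each post-treatment timepoint is tested against 0 h with a
#' two-sided Student (pooled-variance) t-test on per-replicate treated vs
#' untreated delta-Ct values. A gene is
#' called responsive when any timepoint has p below `alpha`; the direction
#' is the sign of the largest-magnitude significant log2 fold change, and
#' the call is doubled ("++"/"--") when that |log2 fold| reaches
#' `tier_log2`. Otherwise the call is "nc".
#'
#' @param rel output of [relativeExpression()] for one or more genes.
#' @param alpha significance level per test (default 0.01, no
#'   multiple-testing correction; set `bonferroni = TRUE` to divide alpha
#'   by the number of timepoint tests per stress).
#' @param tier_log2 |log2 fold| at which "+" becomes "++" (default 3,
#'   i.e. 8-fold).
#' @param bonferroni logical (default FALSE).
#' @return data.frame with one row per gene and one column per stress
#'   present, entries in {nc, +, ++, -, --}.
#' @export
callDifferential <- function(rel, alpha = 0.01, tier_log2 = 3,
                             bonferroni = FALSE) {
  stopifnot(all(c("gene", "stress", "time_h", "replicate_ddct") %in%
                names(rel)))
  genes <- unique(rel$gene)
  stresses <- unique(rel$stress)
  calls <- matrix("nc", length(genes), length(stresses),
                  dimnames = list(genes, stresses))
  for (g in genes) for (s in stresses) {
    sub <- rel[rel$gene == g & rel$stress == s, ]
    if (nrow(sub) == 0L) next
    times <- sort(setdiff(sub$time_h, 0))
    a <- if (bonferroni) alpha / length(times) else alpha
    d0 <- sub$replicate_delta_ct[[which(sub$time_h == 0)]]
    best_lfc <- 0
    for (t in times) {
      i <- which(sub$time_h == t)
      dt <- sub$replicate_delta_ct[[i]]
      if (length(dt) < 2L || length(d0) < 2L)
        stop("need >= 2 replicates for ", g, " under ", s, " at ", t, " h")
      # Student t-test of treated vs untreated delta-Ct
      pt_ <- tryCatch(t.test(dt, d0, var.equal = TRUE)$p.value,
                      error = function(e) NA_real_)
      lfc <- -mean(sub$replicate_ddct[[i]])  # log2 fold change
      if (!is.na(pt_) && pt_ < a && abs(lfc) > abs(best_lfc))
        best_lfc <- lfc
    }
    if (best_lfc != 0) {
      sym <- if (best_lfc > 0) "+" else "-"
      calls[g, s] <- if (abs(best_lfc) >= tier_log2)
        paste0(sym, sym) else sym
    }
  }
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in stresses) df[[s]] <- calls[, s]
  df
}

#' Load the packaged family census fixtures
#'
#' Transcriptions of the survey's printed per-gene tables: the gene
#' inventory (annotation ids, ORF/gene lengths, EST hits, tissue-level
#' expression, cloned CDS) and the per-stress RT-PCR/qPCR call table.
#'
#' @param which one of "genes", "stress_calls", "ortholog_correlations",
#'   "selection_lrt".
#' @return data.frame.
#' @export
wrkyFixture <- function(which = c("genes", "stress_calls",
                                  "ortholog_correlations",
                                  "selection_lrt")) {
  which <- match.arg(which)
  file <- switch(which,
                 genes = "table1_wrky_genes.tsv",
                 stress_calls = "table2_stress_calls.tsv",
                 ortholog_correlations = "table3_ortholog_correlations.tsv",
                 selection_lrt = "table4_selection_lrt.tsv")
  path <- system.file("extdata", file, package = "wrkysurvey",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Summaries of the family census tables
#'
#' Counts derived from the gene-inventory and stress-call fixtures (or any
#' tables of the same shape): genes expressed in at least one tissue,
#' genes with EST support, genes responsive to at least one stress, and
#' per-stress responsive counts.
#'
#' @param genes data.frame shaped like `wrkyFixture("genes")`.
#' @param stress_calls data.frame shaped like
#'   `wrkyFixture("stress_calls")`.
#' @return list with `n_expressed`, `n_est_supported`, `n_responsive`,
#'   `per_stress` (named vector), `n_genes`, `n_tested`.
#' @export
summarizeFamilyTables <- function(genes = wrkyFixture("genes"),
                                  stress_calls =
                                    wrkyFixture("stress_calls")) {
  stopifnot(all(c("gene", "est_hits", "expressed") %in% names(genes)),
            all(c("gene", STRESSES) %in% names(stress_calls)))
  if (anyDuplicated(genes$gene)) stop("malformed fixture: duplicate gene")
  responsive <- apply(stress_calls[, STRESSES] != "nc", 1, any)
  list(n_expressed = sum(genes$expressed == "+", na.rm = TRUE),
       n_est_supported = sum(!is.na(genes$est_hits) & genes$est_hits > 0),
       n_responsive = sum(responsive),
       per_stress = vapply(STRESSES, function(s)
         sum(stress_calls[[s]] != "nc"), integer(1)),
       n_genes = nrow(genes),
       n_tested = nrow(stress_calls))
}

#' Write expression profiles and stress calls as TSV
#'
#' @param rel output of [relativeExpression()].
#' @param calls output of [callDifferential()].
#' @param out_prefix path prefix; writes `<prefix>_profiles.tsv` and
#'   `<prefix>_calls.tsv`.
#' @return invisibly, the two file paths.
#' @export
writeExpressionTables <- function(rel, calls, out_prefix) {
  prof <- rel[, c("gene", "stress", "time_h", "rel_amount", "se")]
  f1 <- paste0(out_prefix, "_profiles.tsv")
  write.table(format(prof, digits = 6), f1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f2 <- paste0(out_prefix, "_calls.tsv")
  write.table(calls, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
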