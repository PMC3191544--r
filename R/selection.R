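# Likelihood-ratio-test bookkeeping and the three-criterion positive-
# selection decision rule over externally supplied codon-model results.
# The codon maximum-likelihood fits themselves (M0/M3/M7/M8) are consumed,
# never computed here.

#' Likelihood ratio test between nested codon models
#'
#' 2 * (lnL_alt - lnL_null) compared with a chi-square upper tail. Standard
#' degrees of freedom for the site-model pairs: 4 for M3 vs M0, 2 for M8
#' vs M7. A slightly negative statistic (improper fit) is floored at 0
#' with a warning.
#'
#' @param lnl_null,lnl_alt model log-likelihoods, or pass `two_dlnl`
#'   directly.
#' @param df degrees of freedom (> 0).
#' @param two_dlnl optional pre-computed statistic (overrides the lnL
#'   pair).
#' @return list with `two_dlnl`, `p_value`, `stars` ("**" p<0.01,
#'   "*" p<0.05, "" otherwise).
#' @export
lrt <- function(lnl_null = NULL, lnl_alt = NULL, df, two_dlnl = NULL) {
  if (df <= 0) stop("df must be positive")
  if (is.null(two_dlnl)) {
    if (is.null(lnl_null) || is.null(lnl_alt))
      stop("supply either (lnl_null, lnl_alt) or two_dlnl")
    two_dlnl <- 2 * (lnl_alt - lnl_null)
  }
  if (two_dlnl < 0) {
    warning("negative 2*delta-lnL floored at 0")
    two_dlnl <- 0
  }
  p <- pchisq(two_dlnl, df = df, lower.tail = FALSE)
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(two_dlnl = two_dlnl, p_value = p, stars = stars)
}

#' Positive-selection verdict for one node
#'
#' A node is called positively selected when all three criteria hold:
#' the M8 estimate of omega for the selected class exceeds 1, at least one
#' site is identified by the Bayes-Empirical-Bayes analysis, and the M8 vs
#' M7 likelihood ratio test is significant at `alpha`.
#'
#' @param m8_omega omega of the M8 selected class.
#' @param n_beb_sites count of BEB-positive sites.
#' @param p_m8_vs_m7 LRT p-value from [lrt()].
#' @param alpha significance level (default 0.05).
#' @return logical verdict.
#' @export
positiveSelectionCall <- function(m8_omega, n_beb_sites, p_m8_vs_m7,
                                  alpha = 0.05) {
  if (any(is.na(c(m8_omega, n_beb_sites, p_m8_vs_m7))))
    stop("missing field in selection result")
  (m8_omega > 1) && (n_beb_sites >= 1) && (p_m8_vs_m7 < alpha)
}

#' Apply the LRT and decision rule to a table of node results
#'
#' Accepts the pre-computed-statistic dialect (columns `two_dlnl_m3_m0`,
#' `two_dlnl_m8_m7`) or raw log-likelihood columns (`lnl_m0`, `lnl_m3`,
#' `lnl_m7`, `lnl_m8`), plus `m8_omega`, `beta_p`, `beta_q`,
#' `n_beb_sites`.
#'
#' @param nodes data.frame, e.g. `wrkyFixture("selection_lrt")`.
#' @param alpha significance level for the verdict (default 0.05).
#' @param df_m3_m0,df_m8_m7 degrees of freedom (defaults 4 and 2).
#' @return the input with added columns `p_m3_m0`, `stars_m3_m0`,
#'   `p_m8_m7`, `stars_m8_m7`, `positive_selection`.
#' @export
selectionTable <- function(nodes, alpha = 0.05, df_m3_m0 = 4,
                           df_m8_m7 = 2) {
  if (any(c("beta_p", "beta_q") %in% names(nodes)) &&
      any(nodes$beta_p <= 0 | nodes$beta_q <= 0, na.rm = TRUE))
    stop("beta distribution parameters must be positive")
  if (!all(c("two_dlnl_m3_m0", "two_dlnl_m8_m7") %in% names(nodes))) {
    need <- c("lnl_m0", "lnl_m3", "lnl_m7", "lnl_m8")
    if (!all(need %in% names(nodes)))
      stop("need either two_dlnl columns or the four lnL columns")
    nodes$two_dlnl_m3_m0 <- 2 * (nodes$lnl_m3 - nodes$lnl_m0)
    nodes$two_dlnl_m8_m7 <- 2 * (nodes$lnl_m8 - nodes$lnl_m7)
  }
  res <- lapply(seq_len(nrow(nodes)), function(i) {
    l1 <- lrt(df = df_m3_m0, two_dlnl = nodes$two_dlnl_m3_m0[i])
    l2 <- lrt(df = df_m8_m7, two_dlnl = nodes$two_dlnl_m8_m7[i])
    data.frame(p_m3_m0 = l1$p_value, stars_m3_m0 = l1$stars,
               p_m8_m7 = l2$p_value, stars_m8_m7 = l2$stars,
               positive_selection = positiveSelectionCall(
                 nodes$m8_omega[i], nodes$n_beb_sites[i], l2$p_value,
                 alpha),
               stringsAsFactors = FALSE)
  })
  cbind(nodes, do.call(rbind, res))
}
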