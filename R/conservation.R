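# Cross-species expression conservation of ortholog pairs: Pearson
# correlation over the seven-timepoint stress series, a randomized-pair
# null, and the ortholog-vs-null contrast.

#' Mean-normalize a raw expression series and rescale to the 0 h control
#'
#' Divides by the series mean and then by the (mean-normalized) 0 h value,
#' so the 0 h entry is exactly 1. Algebraically this equals the direct
#' ratio to the 0 h control.
#'
#' @param raw positive numeric vector of length 7, ordered by the fixed
#'   timepoints 0, 0.5, 1, 3, 6, 12, 24 h.
#' @return numeric vector of length 7 with `[1] == 1`.
#' @export
meanNormalize <- function(raw) {
  if (length(raw) != length(TIMEPOINTS_H))
    stop("expected ", length(TIMEPOINTS_H), " timepoints")
  if (any(raw <= 0)) stop("expression values must be positive")
  x <- raw / mean(raw)
  x / x[1L]
}

#' Pearson correlation of two ortholog expression series
#'
#' Sample Pearson r over the paired 7-timepoint relative-expression
#' values, 0 h included by default.
#'
#' @param cs,at numeric vectors of length 7 (same stress, same timepoint
#'   order). If either has zero variance the correlation is undefined and
#'   returned as `NA` with `defined = FALSE`.
#' @param cs_stress,at_stress optional stress tags; a mismatch is an
#'   error.
#' @param include_zero logical, keep the 0 h point (default TRUE).
#' @param log_scale logical, correlate log2 values instead of ratios.
#' @return list with `r` and `defined`.
#' @export
pairCorrelation <- function(cs, at, cs_stress = NULL, at_stress = NULL,
                            include_zero = TRUE, log_scale = FALSE) {
  if (!is.null(cs_stress) && !is.null(at_stress) &&
      !identical(cs_stress, at_stress))
    stop("stress mismatch: ", cs_stress, " vs ", at_stress)
  stopifnot(length(cs) == length(at))
  if (!include_zero) { cs <- cs[-1L]; at <- at[-1L] }
  if (log_scale) { cs <- log2(cs); at <- log2(at) }
  if (sd(cs) == 0 || sd(at) == 0)
    return(list(r = NA_real_, defined = FALSE))
  list(r = cor(cs, at), defined = TRUE)
}

#' Correlations for a table of ortholog pairs
#'
#' @param pairs data.frame with `cs_gene`, `at_gene`, `stress`.
#' @param cs_profiles,at_profiles data.frames with columns `gene`,
#'   `stress`, and the 7 value columns `t0 ... t24` (see
#'   [genOrthologProfiles()] for the writer).
#' @inheritParams pairCorrelation
#' @return `pairs` with an added column `r`.
#' @export
orthologCorrelations <- function(pairs, cs_profiles, at_profiles,
                                 include_zero = TRUE, log_scale = FALSE) {
  val_cols <- grep("^t", names(cs_profiles), value = TRUE)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    cs <- cs_profiles[cs_profiles$gene == pairs$cs_gene[i] &
                        cs_profiles$stress == pairs$stress[i], val_cols]
    at <- at_profiles[at_profiles$gene == pairs$at_gene[i] &
                        at_profiles$stress == pairs$stress[i], val_cols]
    if (nrow(cs) != 1L || nrow(at) != 1L) return(NA_real_)
    pairCorrelation(as.numeric(cs[1L, ]), as.numeric(at[1L, ]),
                    include_zero = include_zero,
                    log_scale = log_scale)$r
  }, numeric(1))
  pairs$r <- r
  pairs
}

#' Randomized-pair null distribution of expression correlations
#'
#' Draws `n` random cross-species gene pairs (uniform, with replacement)
#' from the two pools of stress-induced expression series and records the
#' Pearson correlation of each. By default a draw matches stresses: a
#' series is drawn from the first pool, then a partner of the same stress
#' from the second pool.
#'
#' @param cs_pool,at_pool data.frames with `gene`, `stress` and 7 value
#'   columns `t0 ... t24`; both non-empty.
#' @param n number of random pairs (default 100).
#' @param seed integer seed; the draw is reproducible.
#' @param stress_matched logical (default TRUE).
#' @param include_zero,log_scale passed to [pairCorrelation()].
#' @return list with `r_values` (length `n`, NA where undefined),
#'   `mean_r`, `n`, `seed`.
#' @export
randomPairNull <- function(cs_pool, at_pool, n = 100L, seed = 1L,
                           stress_matched = TRUE, include_zero = TRUE,
                           log_scale = FALSE) {
  if (nrow(cs_pool) == 0L || nrow(at_pool) == 0L) stop("empty pool")
  val_cols <- grep("^t", names(cs_pool), value = TRUE)
  set.seed(as.integer(seed))
  r <- numeric(n)
  for (k in seq_len(n)) {
    i <- sample.int(nrow(cs_pool), 1L)
    cand <- if (stress_matched)
      which(at_pool$stress == cs_pool$stress[i]) else seq_len(nrow(at_pool))
    if (length(cand) == 0L)
      stop("no partner series for stress ", cs_pool$stress[i])
    j <- cand[sample.int(length(cand), 1L)]
    r[k] <- pairCorrelation(as.numeric(cs_pool[i, val_cols]),
                            as.numeric(at_pool[j, val_cols]),
                            include_zero = include_zero,
                            log_scale = log_scale)$r
  }
  list(r_values = r, mean_r = mean(r, na.rm = TRUE), n = n,
       seed = as.integer(seed))
}

#' Compare ortholog correlations with the randomized null
#'
#' Welch two-sample t-test of the ortholog r values against the null r
#' values; means are reported to 2 decimals alongside full precision.
#'
#' @param ortholog_rs numeric vector of ortholog-pair correlations
#'   (length >= 2).
#' @param null a list from [randomPairNull()] (or any list with
#'   `r_values`).
#' @return list with `mean_ortholog_r`, `mean_null_r` (2 decimals),
#'   `mean_ortholog_r_full`, `mean_null_r_full`, `p_value`.
#' @export
compareToNull <- function(ortholog_rs, null) {
  ortholog_rs <- ortholog_rs[!is.na(ortholog_rs)]
  null_rs <- null$r_values[!is.na(null$r_values)]
  if (length(ortholog_rs) < 2L || length(null_rs) < 2L)
    stop("need at least 2 correlations on each side")
  if (var(ortholog_rs) == 0 && var(null_rs) == 0)
    stop("degenerate variance in both samples")
  tt <- t.test(ortholog_rs, null_rs)        # Welch
  list(mean_ortholog_r = round(mean(ortholog_rs), 2),
       mean_null_r = round(mean(null_rs), 2),
       mean_ortholog_r_full = mean(ortholog_rs),
       mean_null_r_full = mean(null_rs),
       p_value = tt$p.value)
}

#' Summary of an ortholog-correlation table
#'
#' @param datasets data.frame with columns `cs_gene` and `r` (one row per
#'   ortholog-pair-by-stress dataset), e.g.
#'   `wrkyFixture("ortholog_correlations")`.
#' @return list with `mean_r` (2 decimals), `n_gt_0.5`, `n_datasets`,
#'   `n_cs_genes`.
#' @export
table3Summary <- function(datasets = wrkyFixture("ortholog_correlations")) {
  stopifnot(all(c("cs_gene", "r") %in% names(datasets)))
  list(mean_r = round(mean(datasets$r), 2),
       n_gt_0.5 = sum(datasets$r > 0.5),
       n_datasets = nrow(datasets),
       n_cs_genes = length(unique(datasets$cs_gene)))
}
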