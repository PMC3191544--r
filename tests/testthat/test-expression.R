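make_ct <- function(target_ct, ref_ct = 20, times = c(0, 3),
                    reps = 2, gene = "g1", stress = "cold") {
  # target_ct: matrix times x reps (recycled)
  rows <- list()
  for (r in seq_len(reps)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = "ref", stress = stress, time_h = times, replicate = r,
      ct = ref_ct, is_reference = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, stress = stress, time_h = times, replicate = r,
      ct = target_ct, is_reference = FALSE)
  }
  do.call(rbind, rows)
}

test_that("relativeExpression reproduces the ddCt arithmetic", {
  # target 26/ref 20 at 0 h, target 24/ref 20 at t: ddCt = 4-6 = -2 -> 4.0
  ct <- make_ct(target_ct = c(26, 24))
  out <- relativeExpression(ct)
  expect_equal(out$rel_amount[out$time_h == 3], 4.0)
  expect_equal(out$ddct[out$time_h == 3], -2)
  expect_equal(out$delta_ct[out$time_h == 0], 6)
  # 0 h is exactly 1 by construction
  expect_equal(out$rel_amount[out$time_h == 0], 1.0)
  expect_equal(out$ddct[out$time_h == 0], 0)
})

test_that("treated identical to untreated gives rel_amount 1 everywhere", {
  ct <- make_ct(target_ct = c(24, 24, 24), times = c(0, 3, 6))
  out <- relativeExpression(ct)
  expect_equal(out$rel_amount, rep(1, 3))
})

test_that("relativeExpression validates its inputs", {
  ct <- make_ct(c(26, 24))
  expect_error(relativeExpression(ct[ct$ct <= 0 | TRUE, ][-1, ]),
               "missing reference.*cold.*0 h")
  bad <- ct; bad$ct[1] <- -1
  expect_error(relativeExpression(bad), "positive")
  two_ref <- rbind(ct, within(ct[ct$is_reference, ], gene <- "ref2"))
  expect_error(relativeExpression(two_ref), "exactly one reference")
})

test_that("callDifferential calls tiers and leaves nulls nc", {
  # planted 10-fold induction at 3 h (ddCt ~ -log2(10)), tiny noise
  set.seed(1)
  lf <- log2(10)
  ct <- do.call(rbind, lapply(1:3, function(r) rbind(
    data.frame(gene = "ref", stress = "cold", time_h = c(0, 3),
               replicate = r, ct = 20 + rnorm(2, 0, 0.1),
               is_reference = TRUE),
    data.frame(gene = "g1", stress = "cold", time_h = c(0, 3),
               replicate = r, ct = c(24, 24 - lf) + rnorm(2, 0, 0.1),
               is_reference = FALSE),
    data.frame(gene = "g2", stress = "cold", time_h = c(0, 3),
               replicate = r, ct = 24 + rnorm(2, 0, 0.1),
               is_reference = FALSE))))
  out <- callDifferential(relativeExpression(ct))
  expect_identical(out$cold[out$gene == "g1"], "++")
  expect_identical(out$cold[out$gene == "g2"], "nc")
  # repression of the same size gives "--"
  ct$ct[ct$gene == "g1" & ct$time_h == 3] <-
    24 + lf + rnorm(3, 0, 0.1)
  out2 <- callDifferential(relativeExpression(ct))
  expect_identical(out2$cold[out2$gene == "g1"], "--")
  # a 2-fold change significant but below the tier gives a single "+"
  ct$ct[ct$gene == "g1" & ct$time_h == 3] <- 23 + rnorm(3, 0, 0.05)
  out3 <- callDifferential(relativeExpression(ct))
  expect_identical(out3$cold[out3$gene == "g1"], "+")
})

test_that("callDifferential needs two replicates", {
  ct <- make_ct(c(26, 24), reps = 1)
  expect_error(callDifferential(relativeExpression(ct)), "replicates")
})

test_that("fixtures load with the documented shapes", {
  t1 <- wrkyFixture("genes")
  expect_identical(nrow(t1), 57L)
  expect_true(all(c("gene", "est_hits", "expressed") %in% names(t1)))
  t2 <- wrkyFixture("stress_calls")
  expect_identical(nrow(t2), 48L)
  expect_true(all(unlist(t2[, c("cold", "salt", "dry")]) %in%
                  c("nc", "+", "++", "-", "--")))
  t3 <- wrkyFixture("ortholog_correlations")
  expect_identical(nrow(t3), 22L)
  t4 <- wrkyFixture("selection_lrt")
  expect_identical(nrow(t4), 8L)
})

test_that("summarizeFamilyTables counts the census", {
  s <- summarizeFamilyTables()
  expect_identical(s$n_genes, 57L)
  expect_identical(s$n_tested, 48L)
  expect_identical(unname(s$per_stress >= 0), rep(TRUE, 3))
  dup <- wrkyFixture("genes")
  dup$gene[2] <- dup$gene[1]
  expect_error(summarizeFamilyTables(genes = dup), "duplicate")
})

test_that("writeExpressionTables emits the two TSVs", {
  ct <- make_ct(c(26, 24))
  rel <- relativeExpression(ct)
  calls <- callDifferential(rel)
  paths <- writeExpressionTables(rel, calls, file.path(tempdir(), "xp"))
  expect_true(all(file.exists(paths)))
  prof <- read.delim(paths[1])
  expect_identical(names(prof),
                   c("gene", "stress", "time_h", "rel_amount", "se"))
})
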