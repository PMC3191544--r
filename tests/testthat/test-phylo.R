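test_that("pairwiseAlignScore reproduces known BLOSUM62 scores", {
  expect_equal(pairwiseAlignScore("WRKY", "WRKY")$score, 28)
  al <- pairwiseAlignScore("WRKYG", "WRKG")
  expect_identical(nchar(al$aligned[1]), nchar(al$aligned[2]))
  expect_error(pairwiseAlignScore("", "WRKY"), "empty")
  expect_error(pairwiseAlignScore("WRKY", "WRKY", matrix = "NOPE"),
               "alignment failed")
})

test_that("centerStarMsa yields equal-length rows preserving residues", {
  seqs <- c(a = "WRKYGQKAAA", b = "WRKYGQKAA", c = "WRKYGQKCCAAA",
            d = "WRKYAAA")
  msa <- centerStarMsa(seqs)
  expect_identical(msa$ids, names(seqs))
  expect_identical(length(unique(nchar(msa$rows))), 1L)
  # once-a-gap merging never reorders or loses residues
  expect_identical(gsub("-", "", msa$rows), unname(seqs))
  expect_true(msa$center %in% names(seqs))
  expect_error(centerStarMsa(c(a = "AA")), "length")
})

test_that("pDistance matches the oracle and excludes gapped columns", {
  rows <- c(x = "WRKY-A", y = "WRKYGA", z = "WRRY-C")
  d <- pDistance(rows)
  expect_equal(d["x", "y"], oracle_pdist(rows[1], rows[2]))
  expect_equal(d["x", "z"], oracle_pdist(rows[1], rows[3]))
  expect_identical(d, t(d))
  expect_identical(unname(diag(d)), rep(0, 3))
  expect_error(pDistance(c(a = "A-", b = "-A")), "comparable")
})

test_that("poissonCorrect applies -log(1-d) and rejects saturation", {
  d <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  expect_equal(poissonCorrect(d), -log(1 - d))
  d[1, 2] <- 1
  expect_error(poissonCorrect(d), "Poisson")
})

test_that("njTree recovers additive distances and validates input", {
  ra <- random_additive(5, seed = 11)
  tr <- njTree(ra$d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(ra$d),
                                                    colnames(ra$d)],
               ra$d, tolerance = 1e-9)
  expect_error(njTree(ra$d[1:2, 1:2]), "at least 3")
  bad <- ra$d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(njTree(bad), "symmetric")
})

test_that("bootstrapSupport saturates on clean signal and is seeded", {
  # two clearly separated clades, many informative columns
  rows <- c(a1 = strrep("A", 30), a2 = strrep("A", 30),
            b1 = strrep("W", 30), b2 = strrep("W", 30),
            c1 = strrep("AW", 15))
  rows <- vapply(seq_along(rows), function(i)
    paste0(rows[i], substr("KRNDE", i, i)), character(1))
  names(rows) <- c("a1", "a2", "b1", "b2", "c1")
  t1 <- suppressWarnings(bootstrapSupport(rows, n_reps = 50, seed = 9))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup >= 0 & sup <= 100))
  t2 <- suppressWarnings(bootstrapSupport(rows, n_reps = 50, seed = 9))
  expect_identical(t1$node.label, t2$node.label)
  t3 <- suppressWarnings(bootstrapSupport(rows, n_reps = 50, seed = 10))
  expect_identical(ape::Ntip(t3), 5L)
})

test_that("identical-per-clade blocks give 100% supports", {
  rows <- c(a1 = strrep("AC", 20), a2 = strrep("AC", 20),
            b1 = strrep("WY", 20), b2 = strrep("WY", 20))
  # perturb one row minimally so distances are not all ties
  substr(rows["a2"], 1, 1) <- "G"
  tr <- bootstrapSupport(rows, n_reps = 100, seed = 2)
  expect_true(all(as.numeric(tr$node.label) == 100))
})

test_that("assignSubgroup picks the smallest supported reference clade", {
  # ((q1,R2a)95,(R2b,(q2,R2c)40)80)
  tr <- ape::read.tree(text = "((q1:1,R2a:1)95:1,(R2b:1,(q2:1,R2c:1)40:1)80:1);")
  refs <- c(R2a = "2a", R2b = "2b", R2c = "2c")
  out <- assignSubgroup(tr, refs, threshold = 50)
  expect_identical(out[["q1"]], "2a")
  # q2's smallest supported clade contains refs of two subgroups -> mixed
  expect_identical(out[["q2"]], "unclassified")
  # lowering the threshold lets q2 inherit from the 40-support clade
  out2 <- assignSubgroup(tr, refs, threshold = 30)
  expect_identical(out2[["q2"]], "2c")
  expect_error(assignSubgroup(tr, c(R9 = "2d")), "missing reference")
})

test_that("assignSubgroup recovers planted subgroups on synthetic domains", {
  set.seed(1)
  tpl <- wrkyTemplateDomains()
  refs <- wrkyReferencePanel()
  refs <- refs[refs %in% c("2a", "2b", "2c", "2d", "2e")]
  ref_seq <- setNames(tpl[unname(refs)], names(refs))
  q_seq <- setNames(tpl[c("2a", "2c", "2e")], c("q2a", "q2c", "q2e"))
  # mutate queries lightly away from their subgroup template
  q_seq[] <- vapply(q_seq, function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(8:19, 3)
    ch[i] <- "A"
    paste(ch, collapse = "")
  }, character(1))
  msa <- centerStarMsa(c(q_seq, ref_seq))
  tr <- suppressWarnings(
    bootstrapSupport(setNames(msa$rows, msa$ids), n_reps = 100, seed = 4))
  out <- assignSubgroup(tr, refs)
  expect_identical(out[c("q2a", "q2c", "q2e")],
                   c(q2a = "2a", q2c = "2c", q2e = "2e"))
})

test_that("writeNewick round-trips topology and labels", {
  tr <- ape::read.tree(text = "((a:1,b:2)90:0.5,(c:1,d:1)70:0.25);")
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  back <- ape::read.tree(f)
  expect_identical(back$tip.label, tr$tip.label)
  expect_identical(back$node.label, tr$node.label)
  expect_equal(back$edge.length, tr$edge.length)
})
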