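test_that("findSignatures reports 0-based positions of every occurrence", {
  expect_identical(findSignatures("MAAWRKYGQKPV"), 3L)
  expect_identical(findSignatures("WRKYGQKXXWRKYGQK"), c(0L, 9L))
  expect_identical(findSignatures("MAAAA"), integer(0))
  expect_identical(findSignatures(""), integer(0))
  expect_identical(findSignatures("WRKYGKK"), integer(0))
  expect_identical(findSignatures("WRKYGKK", c("WRKYGQK", "WRKYGKK")), 0L)
  expect_error(findSignatures("AAA", "WRKY"), "7-mer")
  expect_error(findSignatures("AAA", character(0)), "non-empty")
})

test_that("detectZincFinger finds C2H2 with correct spacings", {
  # signature at 0, then 3 spacer, C, 4x, C, 21x, H, 1x, H
  s <- paste0("WRKYGQK", "AAA",
              "C", "DDDD", "C", strrep("E", 21), "H", "F", "H")
  zf <- detectZincFinger(s, 0L)
  expect_identical(zf$zf_type, "C2H2")
  expect_identical(zf$spacings, c(4L, 21L, 1L))
  expect_identical(zf$zf_end, nchar(s))
})

test_that("detectZincFinger falls back to C2HC and honors the window", {
  s3 <- paste0("WRKYGQK", "AA",
               "C", strrep("D", 7), "C", strrep("E", 25), "H", "FF", "C")
  zf <- detectZincFinger(s3, 0L)
  expect_identical(zf$zf_type, "C2HC")
  expect_identical(zf$spacings, c(7L, 25L, 2L))
  # same finger pushed beyond the 90-residue window is not found
  far <- paste0("WRKYGQK", strrep("A", 95),
                "C", "DDDD", "C", strrep("E", 21), "H", "F", "H")
  expect_null(detectZincFinger(far, 0L))
  expect_null(detectZincFinger("WRKYGQKAAAA", 0L))
  expect_error(detectZincFinger("SHORT", 3L), "out of range")
})

test_that("spacing outside the configured ranges is rejected", {
  # C-C gap of 6 is outside C2H2 (4..5) and inside C2HC (5..8), but the
  # terminal residue H does not fit C2HC (needs C) -> no call
  s <- paste0("WRKYGQK", "A",
              "C", strrep("D", 6), "C", strrep("E", 21), "H", "F", "H")
  expect_null(detectZincFinger(s, 0L))
  # widening the C2H2 gap1 range recovers it
  cfg <- zincFingerConfig(c2h2 = list(gap1 = c(4L, 6L), gap2 = c(21L, 23L),
                                      gap3 = c(1L, 1L)))
  expect_identical(detectZincFinger(s, 0L, cfg)$zf_type, "C2H2")
})

test_that("scanDomains pads upstream, clips at 0 and tags terminals", {
  core <- paste0("WRKYGQK", "AAA",
                 "C", "DDDD", "C", strrep("E", 21), "H", "F", "H")
  one <- scanDomains("p1", paste0("MM", core))
  expect_identical(nrow(one), 1L)
  expect_identical(one$domain_start, 0L)     # 2 - pad 2
  expect_identical(one$terminal_tag, "only")
  expect_identical(one$signature_seq, "WRKYGQK")
  clip <- scanDomains("p2", core)            # signature at 0, pad clipped
  expect_identical(clip$domain_start, 0L)
  two <- scanDomains("p3", paste0("MMMM", core, "GGGG", core))
  expect_identical(two$terminal_tag, c("N", "C"))
  none <- scanDomains("p4", "MMMM")
  expect_identical(nrow(none), 0L)
})

test_that("classifyGroup implements the domain-complement rules", {
  d2 <- data.frame(zf_type = c("C2H2", "C2H2"))
  expect_identical(classifyGroup("a", d2)$group, "1")
  expect_identical(classifyGroup("b", data.frame(zf_type = "C2H2"))$group, "2")
  expect_identical(classifyGroup("c", data.frame(zf_type = "C2HC"))$group, "3")
  expect_identical(classifyGroup("d", d2[0, , drop = FALSE])$group,
                   "unclassified")
  mixed <- data.frame(zf_type = c("C2H2", "C2HC"))
  out <- classifyGroup("e", mixed)
  expect_identical(out$group, "unclassified")
  expect_match(out$evidence, "ambiguous")
})

test_that("scanProteome validates ids and returns a coherent container", {
  p <- genProteome(group_counts = c(`1` = 2L, `2c` = 2L, `3` = 1L),
                   n_decoys = 4L, seed = 3)
  sc <- scanProteome(p$proteins)
  expect_s4_class(sc, "WrkyScanResult")
  g <- groupCalls(sc)
  fam <- p$truth[p$truth$kind == "family", ]
  expect_identical(g$group[match(fam$protein_id, g$protein_id)], fam$group)
  expect_true(all(g$group[grepl("DECOY", g$protein_id)] == "unclassified"))
  # AAStringSet input accepted
  sc2 <- scanProteome(Biostrings::AAStringSet(p$proteins))
  expect_identical(domainTable(sc2), domainTable(sc))
  expect_error(scanProteome(setNames(c("AA", "AA"), c("x", "x"))), "unique")
  expect_error(scanProteome(setNames("", "x")), "empty")
})

test_that("buildPssm matches the hand-computed log-odds", {
  pssm <- buildPssm(c("AC", "AD"))
  # column 1: A seen 2/2; score = log2((2 + 0.05*0.05)/(2 + 0.05)/0.05)
  expect_equal(unname(pssm@logOdds["A", 1]), log2(2.0025 / 2.05 / 0.05),
               tolerance = 1e-12)
  # column 2: C seen once of 2; unseen residue scores below 0
  expect_equal(unname(pssm@logOdds["C", 2]), log2(1.0025 / 2.05 / 0.05),
               tolerance = 1e-12)
  expect_lt(pssm@logOdds["W", 2], 0)
  expect_equal(maxPssmScore(pssm),
               unname(pssm@logOdds["A", 1] + pssm@logOdds["C", 2]),
               tolerance = 1e-12)
  expect_equal(pssm@scoreThreshold, 0.6 * maxPssmScore(pssm),
               tolerance = 1e-12)
  expect_error(buildPssm("A"), "at least 2")
  expect_error(buildPssm(c("A", "AA")), "equal length")
})

test_that("buildPssm drops majority-gap columns", {
  pssm <- buildPssm(c("A-C", "A-C", "AGC"))   # middle column 2/3 gaps
  expect_identical(pssm@length, 2L)
  half <- buildPssm(c("A-C", "AGC"))          # 50% gaps are kept
  expect_identical(half@length, 3L)
  expect_error(buildPssm(c("--", "--", "-A")), "gapped away")
})

test_that("pssmScore agrees with the brute-force oracle and handles X", {
  pssm <- buildPssm(c("WRKY", "WRKY", "WRKF"))
  s <- "MMWRKYGGWRKFXX"
  got <- pssmScore(pssm, s)
  expect_equal(got$best_score, oracle_best_window(pssm, s),
               tolerance = 1e-12)
  expect_identical(got$best_start, 2L)
  expect_identical(length(got$scores), nchar(s) - 4L + 1L)
  # unknown residues contribute 0
  expect_equal(pssmScore(pssm, "XXXX")$best_score, 0, tolerance = 1e-12)
  short <- pssmScore(pssm, "WR")
  expect_identical(short$best_score, -Inf)
})

test_that("iterativeSearch converges monotonically; seeds-only fixpoint", {
  p <- genProteome(group_counts = c(`2c` = 4L, `3` = 2L), n_decoys = 10L,
                   seed = 5)
  seeds <- wrkyTemplateDomains(trim_to_common_length = TRUE)
  it <- iterativeSearch(p$proteins, unname(seeds))
  fam <- p$truth$protein_id[p$truth$kind == "family"]
  expect_setequal(it$members, fam)
  # profile already at fixpoint when nothing in the proteome matches
  empty <- iterativeSearch(setNames(strrep("A", 60), "x"), unname(seeds))
  expect_identical(empty$rounds, 1L)
  expect_identical(empty$members, character(0))
  # threshold -Inf admits everything
  all_in <- iterativeSearch(p$proteins, unname(seeds),
                            threshold_frac = -Inf)
  expect_setequal(all_in$members, names(p$proteins))
})

test_that("writeDomainTable writes 1-based TSV and 0-based BED", {
  p <- genProteome(group_counts = c(`2c` = 2L), n_decoys = 0L, seed = 1)
  sc <- scanProteome(p$proteins)
  pre <- file.path(tempdir(), "scan_out")
  writeDomainTable(sc, pre)
  tsv <- read.delim(paste0(pre, "_domains.tsv"))
  bed <- read.delim(paste0(pre, "_domains.bed"), header = FALSE)
  d <- domainTable(sc)
  expect_identical(tsv$start, d$domain_start + 1L)
  expect_identical(bed$V2, d$domain_start)
  expect_identical(bed$V3, d$domain_end)
})
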