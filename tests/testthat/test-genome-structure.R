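test_that("assignNames numbers by chromosome order then appends unplaced", {
  loci <- data.frame(
    gene_id = c("g_far", "g_near", "g_chr2", "g_unp_lo", "g_unp_hi"),
    chromosome = c("chr1", "chr1", "chr2", NA, NA),
    start = c(500L, 100L, 50L, NA, NA),
    end = c(600L, 200L, 80L, NA, NA),
    search_score = c(NA, NA, NA, 10, 90))
  nm <- assignNames(loci, prefix = "CsWRKY")
  expect_identical(unname(nm[c("g_near", "g_far", "g_chr2",
                               "g_unp_hi", "g_unp_lo")]),
                   paste0("CsWRKY", 1:5))
  # explicit chromosome order is honored
  nm2 <- assignNames(loci, chrom_order = c("chr2", "chr1"))
  expect_identical(unname(nm2["g_chr2"]), "CsWRKY1")
  expect_error(assignNames(rbind(loci, loci[1, ])), "duplicate")
  expect_error(assignNames(loci, chrom_order = "chr1"), "outside")
})

test_that("tandemArrays finds maximal runs within the gap limit", {
  loci <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    chromosome = c("c1", "c1", "c1", "c1", "c2"),
    start = c(0L, 10000L, 200000L, 220000L, 0L),
    end = c(5000L, 15000L, 210000L, 230000L, 1000L))
  arr <- tandemArrays(loci, max_gap_bp = 50000)
  expect_identical(arr, list(c("a", "b"), c("c", "d")))
  # gap exactly at the limit still clusters; one over does not
  l2 <- data.frame(gene_id = c("x", "y"), chromosome = "c1",
                   start = c(0L, 51000L), end = c(1000L, 52000L))
  expect_identical(tandemArrays(l2), list(c("x", "y")))
  l2$start[2] <- 51001L
  expect_identical(tandemArrays(l2), list())
  # overlapping genes count as gap 0
  l3 <- data.frame(gene_id = c("p", "q"), chromosome = "c1",
                   start = c(0L, 500L), end = c(1000L, 1500L))
  expect_identical(tandemArrays(l3, max_gap_bp = 0), list(c("p", "q")))
})

test_that("mapDomainIntrons computes offsets, phase and domain position", {
  # 2 exons: 96 nt + 54 nt = 150 nt = 50 codons; intron after codon 32
  exons <- data.frame(start = c(0L, 596L), end = c(96L, 650L))
  out <- mapDomainIntrons(exons, "+", domain_start = 10L,
                          domain_end = 45L, protein_length = 50L)
  expect_identical(nrow(out), 1L)
  expect_identical(out$cds_offset, 96L)
  expect_identical(out$phase, 0L)
  expect_identical(out$length_bp, 500L)
  expect_identical(out$domain_codon_offset, 32L - 10L)
  # intron exactly at the domain start boundary is outside (half-open)
  at_start <- mapDomainIntrons(exons, "+", domain_start = 32L,
                               domain_end = 45L)
  expect_true(is.na(at_start$domain_codon_offset))
  # outside the domain entirely
  outside <- mapDomainIntrons(exons, "+", domain_start = 40L,
                              domain_end = 50L)
  expect_true(is.na(outside$domain_codon_offset))
})

test_that("mapDomainIntrons respects minus-strand transcription order", {
  # minus strand: transcription starts at the rightmost exon
  exons <- data.frame(start = c(0L, 596L), end = c(96L, 650L))
  out <- mapDomainIntrons(exons, "-", domain_start = 0L, domain_end = 50L)
  expect_identical(out$cds_offset, 54L)      # rightmost exon first
  expect_identical(out$phase, 0L)
  expect_identical(out$domain_codon_offset, 18L)
  # validation
  expect_error(mapDomainIntrons(exons, "+", 0L, 50L, protein_length = 10L),
               "inconsistent")
  one <- mapDomainIntrons(exons[1, , drop = FALSE], "+", 0L, 32L)
  expect_identical(nrow(one), 0L)
  expect_error(mapDomainIntrons(data.frame(start = c(0L, 50L),
                                           end = c(60L, 80L)), "+", 0L, 10L),
               "overlap")
})

test_that("domainIntronStats summarizes domain-internal introns", {
  introns <- data.frame(length_bp = c(100L, 300L, 700L),
                        domain_codon_offset = c(10L, NA, 30L))
  s <- domainIntronStats(introns)
  expect_equal(s$mean_bp, 400)
  expect_equal(s$median_bp, 400)
  expect_identical(s$n, 2L)
  empty <- domainIntronStats(introns[2, , drop = FALSE])
  expect_true(is.na(empty$mean_bp))
})

test_that("GFF3 writer/reader round-trip and validate", {
  gm <- genGeneModels(n_genes = 3, seed = 9)
  f <- tempfile(fileext = ".gff3")
  writeGeneModelsGff3(gm$models$Cs, f)
  expect_identical(readLines(f)[1], "##gff-version 3")
  back <- readGeneModelsGff3(f)
  expect_identical(names(back), names(gm$models$Cs))
  for (id in names(back))
    expect_identical(back[[id]]$exons, gm$models$Cs[[id]]$exons)
  writeLines(c("##gff-version 3", "too\tfew\tfields"), f)
  expect_error(readGeneModelsGff3(f), "malformed")
})

test_that("generated gene models carry the planted conserved intron", {
  gm <- genGeneModels(n_genes = 5, seed = 10)
  tt <- gm$truth
  for (i in seq_len(nrow(tt))) {
    m <- gm$models[[tt$species[i]]][[tt$gene_id[i]]]
    out <- mapDomainIntrons(m$exons, m$strand, tt$domain_start[i],
                            tt$domain_end[i],
                            protein_length = nchar(gm$proteins[tt$gene_id[i]]))
    expect_identical(out$domain_codon_offset, tt$intron_codon_offset[i])
    expect_identical(out$length_bp, tt$intron_length[i])
  }
  # species intron-length contrast roughly matches the generator means
  expect_gt(mean(tt$intron_length[tt$species == "Cs"]),
            2 * mean(tt$intron_length[tt$species == "At"]))
})
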