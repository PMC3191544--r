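# Chromosome-order gene naming, tandem-array detection, domain-relative
# intron mapping, and a minimal GFF3 dialect for gene models.
# Coordinates are 0-based half-open internally; GFF3 I/O is 1-based
# inclusive.

#' Name family genes by chromosome order
#'
#' Genes placed on chromosomes are sorted by (chromosome order, start,
#' end, gene_id) and numbered prefix+1 ... prefix+k; unplaced genes
#' (chromosome NA) are appended in order of decreasing search score.
#'
#' @param loci data.frame with `gene_id`, `chromosome` (NA = unplaced),
#'   `start`, `end` (0-based half-open), and `search_score` for unplaced
#'   ranking.
#' @param prefix name prefix, e.g. "CsWRKY".
#' @param chrom_order optional character vector giving the chromosome
#'   sort order (default: natural sort of the labels present).
#' @return named character vector: gene_id -> assigned name.
#' @export
assignNames <- function(loci, prefix = "CsWRKY", chrom_order = NULL) {
  if (anyDuplicated(loci$gene_id)) stop("duplicate gene_id")
  placed <- loci[!is.na(loci$chromosome), , drop = FALSE]
  unplaced <- loci[is.na(loci$chromosome), , drop = FALSE]
  if (is.null(chrom_order))
    chrom_order <- sort(unique(placed$chromosome))
  if (!all(placed$chromosome %in% chrom_order))
    stop("chromosome label outside declared order")
  placed <- placed[order(match(placed$chromosome, chrom_order),
                         placed$start, placed$end, placed$gene_id), ,
                   drop = FALSE]
  unplaced <- unplaced[order(-unplaced$search_score, unplaced$gene_id), ,
                       drop = FALSE]
  ids <- c(placed$gene_id, unplaced$gene_id)
  setNames(paste0(prefix, seq_along(ids)), ids)
}

#' Detect tandem arrays of family genes
#'
#' Maximal runs of two or more same-chromosome genes whose successive
#' inter-gene gaps (next start minus previous end, floored at 0) are at
#' most `max_gap_bp`.
#'
#' @param loci data.frame as in [assignNames()] (unplaced genes ignored).
#' @param max_gap_bp maximum gap between neighbours (default 50000).
#' @return list of character vectors of gene ids (possibly empty list).
#' @export
tandemArrays <- function(loci, max_gap_bp = 50000) {
  loci <- loci[!is.na(loci$chromosome), , drop = FALSE]
  clusters <- list()
  for (chr in unique(loci$chromosome)) {
    sub <- loci[loci$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    run <- sub$gene_id[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      gap <- max(0, sub$start[i] - sub$end[i - 1L])
      if (gap <= max_gap_bp) {
        run <- c(run, sub$gene_id[i])
      } else {
        if (length(run) >= 2L) clusters[[length(clusters) + 1L]] <- run
        run <- sub$gene_id[i]
      }
    }
    if (length(run) >= 2L) clusters[[length(clusters) + 1L]] <- run
  }
  clusters
}

#' Map introns onto a protein's WRKY domain codon span
#'
#' Introns are the gaps between consecutive coding exons. Each intron is
#' reported with its coding-sequence offset, phase (offset mod 3), and,
#' when it falls strictly inside the domain's codon span, the 0-based
#' codon offset within the domain. An intron exactly at the domain start
#' boundary is outside (half-open convention).
#'
#' @param exons data.frame with `start`, `end` (0-based half-open genomic
#'   coordinates of the coding exons, ascending).
#' @param strand "+" or "-".
#' @param domain_start,domain_end protein-coordinate codon span of the
#'   domain (0-based half-open), as in [domainTable()].
#' @param protein_length optional; when given, the summed exon length must
#'   equal 3 * protein_length (or plus one stop codon).
#' @return data.frame with one row per intron: `index`, `intron_start`,
#'   `intron_end`, `length_bp`, `cds_offset`, `phase`,
#'   `domain_codon_offset` (NA when outside the domain).
#' @export
mapDomainIntrons <- function(exons, strand = "+", domain_start,
                             domain_end, protein_length = NULL) {
  stopifnot(all(exons$end > exons$start))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(head(exons$end, -1) > tail(exons$start, -1)))
    stop("exons overlap")
  lens <- exons$end - exons$start
  if (!is.null(protein_length)) {
    tot <- sum(lens)
    if (tot != 3L * protein_length && tot != 3L * (protein_length + 1L))
      stop("exon structure inconsistent with protein length")
  }
  n <- nrow(exons)
  if (n < 2L)
    return(data.frame(index = integer(), intron_start = integer(),
                      intron_end = integer(), length_bp = integer(),
                      cds_offset = integer(), phase = integer(),
                      domain_codon_offset = integer()))
  # CDS order follows transcription
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  cum <- cumsum(lens[ord])
  out <- lapply(seq_len(n - 1L), function(k) {
    up <- ord[k]; down <- ord[k + 1L]
    i_start <- if (strand == "+") exons$end[up] else exons$end[down]
    i_end <- if (strand == "+") exons$start[down] else exons$start[up]
    off <- cum[k]                          # nt offset into the CDS
    dom_nt <- c(3L * domain_start, 3L * domain_end)
    inside <- off > dom_nt[1L] && off < dom_nt[2L]
    data.frame(index = k,
               intron_start = i_start, intron_end = i_end,
               length_bp = i_end - i_start,
               cds_offset = off, phase = off %% 3L,
               domain_codon_offset = if (inside)
                 (off - dom_nt[1L]) %/% 3L else NA_integer_)
  })
  do.call(rbind, out)
}

#' Summary statistics for domain-internal intron lengths
#'
#' @param introns data.frame from [mapDomainIntrons()] (rows may be pooled
#'   over genes).
#' @return list with `mean_bp` and `median_bp` of introns inside the
#'   domain, and `n`.
#' @export
domainIntronStats <- function(introns) {
  inside <- introns[!is.na(introns$domain_codon_offset), , drop = FALSE]
  list(mean_bp = if (nrow(inside)) mean(inside$length_bp) else NA_real_,
       median_bp = if (nrow(inside)) median(inside$length_bp) else NA_real_,
       n = nrow(inside))
}

#' Write gene models as GFF3
#'
#' Minimal gene/mRNA/CDS dialect, 1-based inclusive coordinates per the
#' GFF3 specification.
#'
#' @param models list of gene models; each a list with `gene_id`,
#'   `chromosome`, `strand`, `exons` (data.frame `start`, `end`, 0-based
#'   half-open).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGeneModelsGff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    g0 <- min(ex$start); g1 <- max(ex$end)
    lines <- c(lines,
      sprintf("%s\twrkysurvey\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chromosome, g0 + 1L, g1, m$strand, m$gene_id),
      sprintf("%s\twrkysurvey\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              m$chromosome, g0 + 1L, g1, m$strand, m$gene_id, m$gene_id))
    phase <- 0L
    ord <- if (m$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    for (k in seq_along(ord)) {
      i <- ord[k]
      lines <- c(lines,
        sprintf("%s\twrkysurvey\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
                m$chromosome, ex$start[i] + 1L, ex$end[i], m$strand,
                phase, m$gene_id, m$gene_id))
      phase <- (3L - ((ex$end[i] - ex$start[i]) - phase) %% 3L) %% 3L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3 written by [writeGeneModelsGff3()]
#'
#' @param path GFF3 file.
#' @return list of gene models in the same shape as the writer input
#'   (exons 0-based half-open, ascending).
#' @export
readGeneModelsGff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t")
  bad <- vapply(f, length, integer(1)) != 9L
  if (any(bad)) stop("malformed GFF3 line")
  type <- vapply(f, `[[`, character(1), 3L)
  models <- list()
  for (x in f[type == "gene"]) {
    id <- sub("^ID=", "", strsplit(x[9L], ";")[[1L]][1L])
    models[[id]] <- list(gene_id = id, chromosome = x[1L],
                         strand = x[7L],
                         exons = data.frame(start = integer(),
                                            end = integer()))
  }
  for (x in f[type == "CDS"]) {
    parent <- sub("\\.t1$", "",
                  sub("^Parent=", "",
                      grep("^Parent=", strsplit(x[9L], ";")[[1L]],
                           value = TRUE)[1L]))
    models[[parent]]$exons <- rbind(
      models[[parent]]$exons,
      data.frame(start = as.integer(x[4L]) - 1L,
                 end = as.integer(x[5L])))
  }
  for (id in names(models)) {
    ex <- models[[id]]$exons
    models[[id]]$exons <- ex[order(ex$start), , drop = FALSE]
    rownames(models[[id]]$exons) <- NULL
  }
  models
}
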