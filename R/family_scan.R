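# Domain detection, zinc-finger typing, group classification and the
# iterative PSSM family search.

#' Default zinc-finger spacing configuration
#'
#' Spacing ranges (number of residues between the metal-coordinating
#' positions) for the two zinc-finger patterns found in WRKY domains:
#' C2H2 = C-x(4..5)-C-x(21..23)-H-x(1)-H and
#' C2HC = C-x(5..8)-C-x(23..28)-H-x(1..2)-C. The search window is the
#' stretch of residues scanned downstream of the WRKYGQK signature.
#'
#' @param c2h2,c2hc lists with elements `gap1`, `gap2`, `gap3`, each a
#'   length-2 integer range.
#' @param window integer, residues scanned downstream of the signature.
#' @return a list usable as the `zf_config` argument of [detectZincFinger()]
#'   and [scanDomains()].
#' @export
zincFingerConfig <- function(c2h2 = list(gap1 = c(4L, 5L),
                                         gap2 = c(21L, 23L),
                                         gap3 = c(1L, 1L)),
                             c2hc = list(gap1 = c(5L, 8L),
                                         gap2 = c(23L, 28L),
                                         gap3 = c(1L, 2L)),
                             window = 90L) {
  stopifnot(window >= 10)
  list(c2h2 = c2h2, c2hc = c2hc, window = as.integer(window))
}

#' Locate WRKY signature heptapeptides in a protein
#'
#' Reports every 0-based position at which one of the allowed 7-mer
#' signature variants occurs. Overlapping occurrences are all reported.
#'
#' @param sequence amino-acid string.
#' @param allowed_variants character vector of 7-mers; default the canonical
#'   `WRKYGQK`.
#' @return sorted integer vector of 0-based start positions (possibly empty).
#' @examples
#' findSignatures("MAAWRKYGQKPV")  # 3
#' @export
findSignatures <- function(sequence, allowed_variants = "WRKYGQK") {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (length(allowed_variants) == 0L)
    stop("allowed_variants must be non-empty")
  if (any(nchar(allowed_variants) != 7L))
    stop("signature variants must be 7-mers")
  if (nchar(sequence) == 0L) return(integer(0))
  hits <- integer(0)
  for (v in allowed_variants) {
    m <- gregexpr(v, sequence, fixed = TRUE)[[1L]]
    if (m[1L] != -1L) hits <- c(hits, as.integer(m) - 1L)
  }
  sort(unique(hits))
}

# Build the (lazy-quantifier) regex for one finger pattern; capture groups
# hold the three gaps so spacings can be read off the match.
.zfRegex <- function(gaps, last_residue) {
  sprintf("C(.{%d,%d}?)C(.{%d,%d}?)H(.{%d,%d}?)%s",
          gaps$gap1[1], gaps$gap1[2],
          gaps$gap2[1], gaps$gap2[2],
          gaps$gap3[1], gaps$gap3[2],
          last_residue)
}

#' Detect the zinc-finger motif downstream of a WRKY signature
#'
#' Scans a window downstream of the signature heptapeptide for the C2H2
#' pattern first, then the C2HC pattern; returns the leftmost match (and the
#' shortest gaps at that position).
#'
#' @param sequence amino-acid string.
#' @param sig_pos 0-based signature position, as returned by
#'   [findSignatures()].
#' @param zf_config spacing configuration from [zincFingerConfig()].
#' @return `NULL` if no finger is found, else a list with `zf_type`
#'   (`"C2H2"` or `"C2HC"`), `spacings` (three integers: C-C gap, C-H gap,
#'   H-terminal gap) and `zf_end` (0-based exclusive end of the finger in
#'   the protein).
#' @export
detectZincFinger <- function(sequence, sig_pos,
                             zf_config = zincFingerConfig()) {
  n <- nchar(sequence)
  if (sig_pos < 0 || sig_pos + 7L > n)
    stop("sig_pos out of range for this sequence")
  from <- sig_pos + 7L                     # 0-based start of search
  win <- substr(sequence, from + 1L, min(n, from + zf_config$window))
  for (ty in c("C2H2", "C2HC")) {
    gaps <- if (ty == "C2H2") zf_config$c2h2 else zf_config$c2hc
    last <- if (ty == "C2H2") "H" else "C"
    m <- regexec(.zfRegex(gaps, last), win, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      lens <- attr(m, "match.length")
      spac <- as.integer(lens[2:4])
      zf_end <- from + (m[1L] - 1L) + lens[1L]   # 0-based exclusive
      return(list(zf_type = ty, spacings = spac, zf_end = zf_end))
    }
  }
  NULL
}

#' Scan one protein for complete WRKY domains
#'
#' A domain is reported for every signature occurrence that has a resolvable
#' zinc finger downstream. The domain span runs from `upstream_pad` residues
#' before the signature (clipped at 0) to the end of the zinc finger,
#' 0-based half-open. Two-domain proteins get terminal tags `N` and `C` in
#' positional order, single-domain proteins `only`.
#'
#' @param protein_id id used in the output rows.
#' @param sequence amino-acid string.
#' @param allowed_variants signature 7-mers, see [findSignatures()].
#' @param zf_config see [zincFingerConfig()].
#' @param upstream_pad residues included before the signature (default 2).
#' @return data.frame with one row per domain (possibly 0 rows); columns as
#'   in [domainTable()].
#' @export
scanDomains <- function(protein_id, sequence,
                        allowed_variants = "WRKYGQK",
                        zf_config = zincFingerConfig(),
                        upstream_pad = 2L) {
  sigs <- findSignatures(sequence, allowed_variants)
  rows <- lapply(sigs, function(s) {
    zf <- detectZincFinger(sequence, s, zf_config)
    if (is.null(zf)) return(NULL)
    data.frame(protein_id = protein_id,
               sig_start = s,
               domain_start = max(0L, s - as.integer(upstream_pad)),
               domain_end = min(nchar(sequence), zf$zf_end),
               signature_seq = substr(sequence, s + 1L, s + 7L),
               zf_type = zf$zf_type,
               zf_gap1 = zf$spacings[1L],
               zf_gap2 = zf$spacings[2L],
               zf_gap3 = zf$spacings[3L],
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(protein_id = character(), sig_start = integer(),
                       domain_start = integer(), domain_end = integer(),
                       signature_seq = character(), zf_type = character(),
                       zf_gap1 = integer(), zf_gap2 = integer(),
                       zf_gap3 = integer(), stringsAsFactors = FALSE)
  rows$terminal_tag <- if (nrow(rows) == 2L) c("N", "C")
                       else rep("only", nrow(rows))
  rows
}

#' Classify a protein into a WRKY group from its scanned domains
#'
#' Two C2H2 domains give group 1; one C2H2 domain group 2 (the 2a-2e
#' subgroup is assigned later by phylogenetic placement, see
#' [assignSubgroup()]); one C2HC domain group 3; no domain leaves the
#' protein unclassified. Mixed or unusual domain complements are
#' unclassified with the triggering evidence recorded.
#'
#' @param protein_id id for the output row.
#' @param domains data.frame from [scanDomains()] for this protein.
#' @return one-row data.frame with `protein_id`, `group`, `n_domains`,
#'   `evidence` (comma-joined rule identifiers).
#' @export
classifyGroup <- function(protein_id, domains) {
  n <- nrow(domains)
  zf <- sort(domains$zf_type)
  if (n == 0L) {
    group <- "unclassified"; ev <- "no_domain"
  } else if (n == 2L && all(zf == "C2H2")) {
    group <- "1"; ev <- "two_domains_C2H2"
  } else if (n == 1L && zf == "C2H2") {
    group <- "2"; ev <- "single_domain_C2H2"
  } else if (n == 1L && zf == "C2HC") {
    group <- "3"; ev <- "single_domain_C2HC"
  } else {
    group <- "unclassified"
    ev <- paste0("ambiguous_domains:", n, ":", paste(zf, collapse = "+"))
  }
  data.frame(protein_id = protein_id, group = group, n_domains = n,
             evidence = ev, stringsAsFactors = FALSE)
}

#' Scan a whole proteome and classify every protein
#'
#' @param proteins a named character vector or [Biostrings::AAStringSet];
#'   names are protein ids and must be unique.
#' @inheritParams scanDomains
#' @return a [WrkyScanResult-class] object.
#' @export
scanProteome <- function(proteins, allowed_variants = "WRKYGQK",
                         zf_config = zincFingerConfig(),
                         upstream_pad = 2L) {
  if (is(proteins, "AAStringSet")) proteins <- as.character(proteins)
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  if (anyDuplicated(names(proteins)))
    stop("protein ids must be unique within a proteome")
  if (any(nchar(proteins) == 0L)) stop("empty protein sequence")
  doms <- lapply(names(proteins), function(id)
    scanDomains(id, proteins[[id]], allowed_variants, zf_config,
                upstream_pad))
  groups <- do.call(rbind, lapply(seq_along(proteins), function(i)
    classifyGroup(names(proteins)[i], doms[[i]])))
  new("WrkyScanResult",
      proteome = AAStringSet(proteins),
      domains = do.call(rbind, doms),
      groups = groups)
}

#' Build a log-odds PSSM from an aligned block of domain sequences
#'
#' Columns with more than 50 percent gaps are dropped. The score of residue
#' a in column j is `log2((count + pc * bg[a]) / (n + pc) / bg[a])` where
#' `count` is the number of rows showing a in column j, `n` the number of
#' non-gap rows in the column, `pc` the pseudocount and `bg` the background
#' frequency. Residues outside the 20-letter alphabet (for instance X)
#' score 0 when a window is evaluated.
#'
#' @param block character vector of >= 2 equal-length gapped sequences.
#' @param pseudocount positive pseudocount weight (default 0.05).
#' @param background named frequency vector over the 20 amino acids
#'   (default uniform).
#' @param threshold_frac family-membership threshold as a fraction of the
#'   maximum attainable window score (default 0.6).
#' @return a [PSSM-class] object.
#' @export
buildPssm <- function(block, pseudocount = 0.05,
                      background = setNames(rep(1 / 20, 20), AA20),
                      threshold_frac = 0.6) {
  if (length(block) < 2L) stop("need at least 2 aligned rows")
  if (length(unique(nchar(block))) != 1L)
    stop("aligned rows must have equal length")
  if (any(background <= 0)) stop("background frequencies must be positive")
  background <- background[AA20]
  background <- background / sum(background)
  mat <- do.call(rbind, strsplit(toupper(block), ""))
  keep <- colMeans(mat == "-") <= 0.5
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) == 0L) stop("all columns gapped away")
  logodds <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    n <- length(col)
    counts <- vapply(AA20, function(a) sum(col == a), integer(1))
    log2((counts + pseudocount * background) /
           (n + pseudocount) / background)
  }, numeric(20))
  rownames(logodds) <- AA20
  pssm <- new("PSSM", length = ncol(logodds), logOdds = logodds,
              background = background, pseudocount = pseudocount,
              scoreThreshold = 0)
  pssm@scoreThreshold <- threshold_frac * maxPssmScore(pssm)
  pssm
}

#' @rdname buildPssm
#' @param pssm a [PSSM-class] object.
#' @return `maxPssmScore()` returns the maximum attainable window score in
#'   bits (sum of column maxima).
#' @export
maxPssmScore <- function(pssm) sum(apply(pssm@logOdds, 2, max))

#' Score every window of a sequence against a PSSM
#'
#' @param pssm a [PSSM-class] object.
#' @param sequence amino-acid string.
#' @return list with `best_score` (the maximum window score; `-Inf` if the
#'   sequence is shorter than the profile), `best_start` (0-based) and
#'   `scores` (vector over all window starts).
#' @export
pssmScore <- function(pssm, sequence) {
  L <- pssm@length
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  if (n < L)
    return(list(best_score = -Inf, best_start = NA_integer_,
                scores = numeric(0)))
  idx <- match(chars, AA20)                 # NA for X etc. -> scores 0
  nwin <- n - L + 1L
  total <- numeric(nwin)
  for (j in seq_len(L)) {
    v <- pssm@logOdds[cbind(idx[j:(j + nwin - 1L)], j)]
    v[is.na(v)] <- 0
    total <- total + v
  }
  b <- which.max(total)
  list(best_score = total[b], best_start = b - 1L, scores = total)
}

#' Iterative PSSM search of a proteome to convergence
#'
#' Starting from an aligned seed block, each round scores every protein
#' with the current profile (best window), admits proteins scoring at or
#' above the threshold, rebuilds the profile from the best windows of all
#' members, and stops when membership no longer changes. Membership is
#' monotone non-decreasing across rounds.
#'
#' @param proteins named character vector or `AAStringSet`.
#' @param seed_block character vector of aligned seed domain sequences.
#' @param pseudocount,background,threshold_frac passed to [buildPssm()];
#'   the threshold is re-derived from each round's profile. Set
#'   `threshold_frac = -Inf` to admit everything.
#' @param max_rounds safety cap (default the proteome size).
#' @return list with `members` (sorted character vector of family protein
#'   ids), `rounds` (number of scoring rounds run) and `pssm` (final
#'   profile).
#' @export
iterativeSearch <- function(proteins, seed_block, pseudocount = 0.05,
                            background = setNames(rep(1 / 20, 20), AA20),
                            threshold_frac = 0.6,
                            max_rounds = NULL) {
  if (is(proteins, "AAStringSet")) proteins <- as.character(proteins)
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  if (is.null(max_rounds)) max_rounds <- max(1L, length(proteins))
  members <- NULL
  block <- seed_block
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    pssm <- buildPssm(block, pseudocount, background,
                      threshold_frac = if (is.finite(threshold_frac))
                        threshold_frac else 0)
    thr <- if (is.finite(threshold_frac)) pssm@scoreThreshold else -Inf
    hits <- lapply(proteins, function(s) pssmScore(pssm, s))
    ok <- vapply(hits, function(h) h$best_score >= thr, logical(1))
    new_members <- sort(union(members, names(proteins)[ok]))
    if (identical(new_members, members)) break   # membership fixpoint
    members <- new_members
    if (rounds >= max_rounds) break
    # rebuild the profile from the best window of every member
    wins <- vapply(members, function(id) {
      h <- hits[[id]]
      substr(proteins[[id]], h$best_start + 1L, h$best_start + pssm@length)
    }, character(1))
    wins <- wins[nchar(wins) == pssm@length]
    new_block <- if (length(wins) >= 2L) unname(wins) else seed_block
    if (identical(sort(new_block), sort(block))) break  # profile fixpoint
    block <- new_block
  }
  list(members = members, rounds = rounds, pssm = pssm)
}

#' Write the per-domain table as TSV and BED6
#'
#' The TSV reports 1-based inclusive coordinates; the BED6 keeps the
#' 0-based half-open convention with the zinc-finger type in the name
#' column.
#'
#' @param scan a [WrkyScanResult-class].
#' @param out_prefix path prefix; writes `<prefix>_domains.tsv` and
#'   `<prefix>_domains.bed`.
#' @return invisibly, the two file paths.
#' @export
writeDomainTable <- function(scan, out_prefix) {
  d <- domainTable(scan)
  g <- groupCalls(scan)
  tsv <- data.frame(protein_id = d$protein_id,
                    start = d$domain_start + 1L,    # 1-based inclusive
                    end = d$domain_end,
                    signature = d$signature_seq,
                    zf_type = d$zf_type,
                    group = g$group[match(d$protein_id, g$protein_id)],
                    stringsAsFactors = FALSE)
  f1 <- paste0(out_prefix, "_domains.tsv")
  write.table(tsv, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(d$protein_id, d$domain_start, d$domain_end,
                    d$zf_type, 0L, "+")
  f2 <- paste0(out_prefix, "_domains.bed")
  write.table(bed, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(f1, f2))
}
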