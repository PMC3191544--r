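# Alignment, distances, neighbor-joining trees, bootstrap support and
# reference-clade subgroup assignment for WRKY domain sequences.

#' Global pairwise alignment of two amino-acid sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, delegated
#' to Biostrings. Defaults follow common practice for protein family work:
#' BLOSUM62, gap open 10, gap extend 1.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param matrix substitution matrix name known to Biostrings
#'   (e.g. "BLOSUM62", "BLOSUM50", "PAM250").
#' @param gap_open,gap_extend non-negative penalty costs.
#' @return list with `score` and `aligned` (character vector of the two
#'   gapped sequences).
#' @examples
#' pairwiseAlignScore("WRKY", "WRKY")$score  # 28 under BLOSUM62
#' @export
pairwiseAlignScore <- function(a, b, matrix = "BLOSUM62",
                               gap_open = 10, gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  pa <- tryCatch(
    Biostrings::pairwiseAlignment(a, b, type = "global",
                                  substitutionMatrix = matrix,
                                  gapOpening = gap_open,
                                  gapExtension = gap_extend),
    error = function(e) stop("alignment failed (unknown matrix? ", matrix,
                             "): ", conditionMessage(e)))
  list(score = score(pa),
       aligned = c(as.character(alignedPattern(pa)),
                   as.character(alignedSubject(pa))))
}

# insert gap columns (0-based positions in the current master string)
.insertGaps <- function(s, pos) {
  if (length(pos) == 0L) return(s)
  chars <- strsplit(s, "")[[1L]]
  out <- character(length(chars) + length(pos))
  take <- rep(TRUE, length(out))
  take[pos + seq_along(pos)] <- FALSE  # pos are pre-insertion indices
  out[!take] <- "-"
  out[take] <- chars
  paste(out, collapse = "")
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence maximizing its summed pairwise alignment
#' score against all others; every other sequence is aligned to the center
#' and merged under the "once a gap, always a gap" rule.
#'
#' @param seqs named character vector of >= 2 sequences (unique names).
#' @inheritParams pairwiseAlignScore
#' @return list with `ids`, `rows` (equal-length gapped strings, same
#'   order as `ids`) and `center` (id of the center sequence).
#' @export
centerStarMsa <- function(seqs, matrix = "BLOSUM62", gap_open = 10,
                          gap_extend = 1) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  n <- length(seqs)
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- pairwiseAlignScore(seqs[[i]], seqs[[j]], matrix, gap_open,
                            gap_extend)$score
    scores[i, j] <- scores[j, i] <- s
  }
  center <- which.max(rowSums(scores))
  master <- seqs[[center]]                    # center row, gaps accumulate
  rows <- list()
  order_others <- setdiff(seq_len(n), center)
  for (k in order_others) {
    al <- pairwiseAlignScore(gsub("-", "", master), seqs[[k]],
                             matrix, gap_open, gap_extend)$aligned
    # map the freshly aligned center (al[1]) onto the gapped master:
    # walk both, inserting master gaps into the new row and new gaps into
    # master and all previously merged rows.
    mold <- strsplit(master, "")[[1L]]
    mnew <- strsplit(al[1L], "")[[1L]]
    rnew <- strsplit(al[2L], "")[[1L]]
    oi <- 1L; ni <- 1L
    out_master <- character(0); out_row <- character(0)
    ins_in_old <- integer(0)                 # where new gap columns land
    while (oi <= length(mold) || ni <= length(mnew)) {
      og <- oi <= length(mold) && mold[oi] == "-"
      ng <- ni <= length(mnew) && mnew[ni] == "-"
      if (og) {                              # old master gap column first
        out_master <- c(out_master, "-"); out_row <- c(out_row, "-")
        oi <- oi + 1L
      } else if (ng) {                       # new gap column in center
        out_master <- c(out_master, "-")
        out_row <- c(out_row, rnew[ni])
        ins_in_old <- c(ins_in_old, oi - 1L)
        ni <- ni + 1L
      } else {                               # same residue in both
        out_master <- c(out_master, mold[oi])
        out_row <- c(out_row, rnew[ni])
        oi <- oi + 1L; ni <- ni + 1L
      }
    }
    rows <- lapply(rows, .insertGaps, pos = ins_in_old)
    master <- paste(out_master, collapse = "")
    rows[[as.character(k)]] <- paste(out_row, collapse = "")
  }
  all_rows <- character(n)
  all_rows[center] <- master
  for (k in order_others) all_rows[k] <- rows[[as.character(k)]]
  list(ids = names(seqs), rows = all_rows, center = names(seqs)[center])
}

#' Pairwise p-distance matrix from an alignment
#'
#' d(i, j) = mismatches / compared columns, where columns with a gap in
#' either row are excluded. A pair with no comparable column is an error.
#'
#' @param rows equal-length gapped strings.
#' @param ids taxon labels (default names of `rows`).
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
pDistance <- function(rows, ids = names(rows)) {
  stopifnot(length(rows) >= 2L, length(unique(nchar(rows))) == 1L)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  m <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns between ", ids[i], " and ", ids[j])
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Poisson-corrected distance from p-distances
#'
#' @param d p-distance matrix from [pDistance()]; entries must be < 1.
#' @return -log(1 - d), the standard Poisson correction for amino acids.
#' @export
poissonCorrect <- function(d) {
  if (any(d >= 1)) stop("p-distance of 1 cannot be Poisson corrected")
  -log(1 - d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Negative branch-length estimates
#' are clamped to zero with a warning. The returned tree is unrooted.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an [ape::phylo] object.
#' @export
njTree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for the bipartitions of an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal node of the full-data tree the
#' percentage of replicates containing its bipartition. During resampling a
#' pair left with no comparable columns gets the maximal p-distance 1
#' rather than failing the replicate.
#'
#' @param rows equal-length gapped strings (named by taxon).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; same seed gives identical supports.
#' @param poisson logical, apply [poissonCorrect()] to distances.
#' @return the full-data NJ tree with `node.label` set to support
#'   percentages in [0, 100].
#' @export
bootstrapSupport <- function(rows, n_reps = 1000L, seed = 42L,
                             poisson = FALSE) {
  stopifnot(n_reps >= 1L)
  ids <- names(rows)
  dist_fun <- function(r) {
    d <- .pDistanceLenient(r, ids)
    if (poisson) poissonCorrect(pmin(d, 0.999)) else d
  }
  full <- njTree(dist_fun(rows))
  ncol_aln <- nchar(rows[[1L]])
  m <- do.call(rbind, strsplit(rows, ""))
  set.seed(as.integer(seed))
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rb <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    names(rb) <- ids
    boots[[b]] <- njTree(dist_fun(rb))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.character(round(100 * counts / n_reps, 1))
  # the root bipartition of an unrooted tree is trivial: present always
  full$node.label[1L] <- "100"
  full
}

# p-distance that tolerates zero-comparable pairs (bootstrap internals)
.pDistanceLenient <- function(rows, ids) {
  m <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    d[i, j] <- d[j, i] <- if (!any(ok)) 1
      else sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

# numeric node supports of a tree; NA where absent/unparseable
.nodeSupports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Assign group-2 subgroups by reference-clade placement
#'
#' Each query leaf inherits the subgroup of the smallest well-supported
#' clade (support >= `threshold`) that contains it together with reference
#' leaves of exactly one subgroup; a clade mixing reference subgroups, or
#' the absence of any qualifying clade, leaves the query unclassified.
#' Unrooted trees are midpoint-rooted first.
#'
#' @param tree an `ape::phylo` with node supports in `node.label`.
#' @param references named character vector: reference leaf -> subgroup
#'   label. At least one reference per subgroup must be in the tree.
#' @param threshold minimum support (default 50).
#' @return named character vector: query leaf -> subgroup or
#'   "unclassified".
#' @export
assignSubgroup <- function(tree, references, threshold = 50) {
  refs <- references[names(references) %in% tree$tip.label]
  missing_sub <- setdiff(unique(references), unique(refs))
  if (length(refs) == 0L || length(missing_sub) > 0L)
    stop("missing reference leaves for subgroup(s): ",
         paste(if (length(refs) == 0L) unique(references) else missing_sub,
               collapse = ", "))
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  nt <- length(tree$tip.label)
  supports <- .nodeSupports(tree)
  queries <- setdiff(tree$tip.label, names(refs))
  tips_below <- phangorn::Descendants(tree, (nt + 1L):(nt + tree$Nnode),
                                      type = "tips")
  out <- setNames(rep("unclassified", length(queries)), queries)
  for (q in queries) {
    tip <- match(q, tree$tip.label)
    anc <- phangorn::Ancestors(tree, tip, type = "all")  # nearest first
    for (node in anc) {
      supp <- supports[node - nt]
      root <- node == nt + 1L
      if (!root && (is.na(supp) || supp < threshold)) next
      leaves <- tree$tip.label[tips_below[[node - nt]]]
      subs <- unique(refs[intersect(leaves, names(refs))])
      if (length(subs) == 0L) next
      if (length(subs) == 1L) out[q] <- subs
      break                                   # smallest qualifying clade
    }
  }
  out
}

#' Reference panel of Arabidopsis WRKY exemplars per group/subgroup
#'
#' One representative per group or subgroup, as commonly used to anchor
#' WRKY domain phylogenies: AtWRKY20 (group 1), 40 (2a), 72 (2b), 50 (2c),
#' 74 (2d), 65 (2e) and 54 (group 3).
#'
#' @return named character vector: reference id -> group label.
#' @export
wrkyReferencePanel <- function() {
  c(AtWRKY20 = "1", AtWRKY40 = "2a", AtWRKY72 = "2b", AtWRKY50 = "2c",
    AtWRKY74 = "2d", AtWRKY65 = "2e", AtWRKY54 = "3")
}

#' Write a tree with supports to Newick
#'
#' Supports are written as internal node labels; branch lengths are kept at
#' 6 significant digits.
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeNewick <- function(tree, path) {
  if (!is.null(tree$edge.length))
    tree$edge.length <- signif(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
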