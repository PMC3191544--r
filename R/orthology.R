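# Ortholog calling: bidirectional best hits, supported cross-species
# clades, and the combined decision rule with N/C-domain congruence for
# two-domain (group 1) proteins.

#' Bidirectional best hits between two gene sets
#'
#' A pair (a, b) is emitted when b is among a's best hits in B and a is
#' among b's best hits in A. Ties for best are all considered; a pair
#' produced through a tie is flagged.
#'
#' @param scores_ab numeric matrix, rows = genes of set A, columns = genes
#'   of set B (dimnames required).
#' @param scores_ba numeric matrix, rows = genes of set B, columns = genes
#'   of set A. Defaults to `t(scores_ab)` (symmetric scoring).
#' @return data.frame with columns `a`, `b`, `tie` (logical).
#' @export
bbhPairs <- function(scores_ab, scores_ba = t(scores_ab)) {
  if (nrow(scores_ab) == 0L || ncol(scores_ab) == 0L)
    stop("empty gene set")
  stopifnot(!is.null(rownames(scores_ab)), !is.null(colnames(scores_ab)))
  A <- rownames(scores_ab); B <- colnames(scores_ab)
  stopifnot(setequal(rownames(scores_ba), B),
            setequal(colnames(scores_ba), A))
  scores_ba <- scores_ba[B, A, drop = FALSE]
  bestB <- lapply(A, function(a) {
    v <- scores_ab[a, ]; B[v == max(v)]
  })
  names(bestB) <- A
  bestA <- lapply(B, function(b) {
    v <- scores_ba[b, ]; A[v == max(v)]
  })
  names(bestA) <- B
  out <- list()
  for (a in A) for (b in bestB[[a]]) {
    if (a %in% bestA[[b]])
      out[[length(out) + 1L]] <- data.frame(
        a = a, b = b,
        tie = length(bestB[[a]]) > 1L || length(bestA[[b]]) > 1L,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(a = character(), b = character(), tie = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Candidate ortholog pairs from supported cross-species clades
#'
#' For every minimal clade whose bootstrap support strictly exceeds the
#' threshold and which contains leaves of both species, all cross-species
#' leaf pairs within the clade are emitted with that clade's support.
#' Pairs only ever contained in clades at or below the threshold are
#' excluded.
#'
#' @param tree `ape::phylo` with percentage supports in `node.label`
#'   (unrooted trees are midpoint-rooted).
#' @param species_of named character vector: leaf -> species tag.
#' @param threshold support cutoff, strict (default 50).
#' @return data.frame with `a` (first species), `b` (second species),
#'   `support`.
#' @export
cladeCandidates <- function(tree, species_of, threshold = 50) {
  stopifnot(all(tree$tip.label %in% names(species_of)))
  sp <- unique(unname(species_of[tree$tip.label]))
  if (length(sp) != 2L)
    stop("tree must contain leaves of exactly 2 species, got ",
         length(sp))
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  nt <- length(tree$tip.label)
  supports <- .nodeSupports(tree)
  tips_below <- phangorn::Descendants(tree, (nt + 1L):(nt + tree$Nnode),
                                      type = "tips")
  qualifies <- vapply(seq_len(tree$Nnode), function(k) {
    supp <- supports[k]
    if (is.na(supp) || supp <= threshold) return(FALSE)
    leaves <- tree$tip.label[tips_below[[k]]]
    length(unique(species_of[leaves])) == 2L
  }, logical(1))
  out <- list()
  for (k in which(qualifies)) {
    node <- nt + k
    inner <- phangorn::Descendants(tree, node, type = "all")
    inner <- inner[inner > nt] - nt
    if (any(qualifies[inner])) next                 # not minimal
    leaves <- tree$tip.label[tips_below[[k]]]
    a <- leaves[species_of[leaves] == sp[1L]]
    b <- leaves[species_of[leaves] == sp[2L]]
    out[[length(out) + 1L]] <- expand.grid(a = a, b = b,
                                           stringsAsFactors = FALSE)
    out[[length(out)]]$support <- supports[k]
  }
  if (length(out) == 0L)
    return(data.frame(a = character(), b = character(),
                      support = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$a, res$b), , drop = FALSE]
}

#' Call ortholog pairs from candidates, BBH and N/C-domain congruence
#'
#' A candidate is accepted when its clade support strictly exceeds the
#' threshold and, for group-1 (two-domain) proteins, the same cross-species
#' pairing is recovered in both the N-terminal-domain and the
#' C-terminal-domain trees. The BBH flag is recorded as corroboration; with
#' `require_bbh = TRUE` it becomes a hard filter. A manual veto list
#' removes pairs excluded on curatorial grounds.
#'
#' @param candidates data.frame from [cladeCandidates()] (columns `a`,
#'   `b`, `support`; `a` is the query-species gene).
#' @param bbh data.frame from [bbhPairs()] (may be empty).
#' @param group_of named character vector: query-species gene -> group.
#' @param nc_trees for group-1 calls, `list(N = tree, C = tree)` with
#'   supports; may be `NULL` when no group-1 candidate is present.
#' @param threshold support cutoff (default 50, strict).
#' @param require_bbh logical (default FALSE).
#' @param veto data.frame or matrix with two columns of pairs to drop.
#' @return data.frame with `cs_id`, `at_id`, `support`, `bbh`, `group`,
#'   `congruent_nc` (NA for non-group-1), ordered by ids.
#' @export
callOrthologs <- function(candidates, bbh = NULL, group_of = NULL,
                          nc_trees = NULL, threshold = 50,
                          require_bbh = FALSE, veto = NULL) {
  if (nrow(candidates) == 0L)
    return(data.frame(cs_id = character(), at_id = character(),
                      support = numeric(), bbh = logical(),
                      group = character(), congruent_nc = logical(),
                      stringsAsFactors = FALSE))
  cand <- candidates[order(candidates$a, candidates$b), , drop = FALSE]
  nc_cand <- lapply(nc_trees, function(tr) {
    sp <- setNames(ifelse(tr$tip.label %in% names(group_of), "cs", "at"),
                   tr$tip.label)
    cladeCandidates(tr, sp, threshold)
  })
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    a <- cand$a[i]; b <- cand$b[i]; supp <- cand$support[i]
    if (supp <= threshold) return(NULL)
    grp <- if (!is.null(group_of) && a %in% names(group_of))
      group_of[[a]] else NA_character_
    congruent <- NA
    if (identical(grp, "1")) {
      if (is.null(nc_trees) ||
          !all(c(a, b) %in% nc_trees$N$tip.label) ||
          !all(c(a, b) %in% nc_trees$C$tip.label))
        stop("group-1 candidate ", a, "/", b,
             " missing from an N/C-domain tree")
      inN <- any(nc_cand$N$a == a & nc_cand$N$b == b)
      inC <- any(nc_cand$C$a == a & nc_cand$C$b == b)
      congruent <- inN && inC
      if (!congruent) return(NULL)
    }
    has_bbh <- !is.null(bbh) && any(bbh$a == a & bbh$b == b)
    if (require_bbh && !has_bbh) return(NULL)
    if (!is.null(veto) &&
        any(veto[, 1L] == a & veto[, 2L] == b)) return(NULL)
    data.frame(cs_id = a, at_id = b, support = supp, bbh = has_bbh,
               group = grp, congruent_nc = congruent,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(cs_id = character(), at_id = character(),
                       support = numeric(), bbh = logical(),
                       group = character(), congruent_nc = logical(),
                       stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  rows
}
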