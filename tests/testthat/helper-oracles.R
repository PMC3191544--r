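# Independent reference implementations used as oracles by the tests.

# textbook Pearson correlation, written out
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force p-distance between two gapped rows
oracle_pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca != "-" & cb != "-"
  sum(ca[ok] != cb[ok]) / sum(ok)
}

# random additive distance matrix from a random binary tree with positive
# branch lengths; returns list(tree, d)
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# brute-force best PSSM window score (independent of pssmScore's loop)
oracle_best_window <- function(pssm, sequence) {
  L <- pssm@length
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) < L) return(-Inf)
  best <- -Inf
  for (s in 1:(length(chars) - L + 1)) {
    tot <- 0
    for (j in 1:L) {
      aa <- chars[s + j - 1]
      tot <- tot + if (aa %in% rownames(pssm@logOdds))
        pssm@logOdds[aa, j] else 0
    }
    best <- max(best, tot)
  }
  best
}
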