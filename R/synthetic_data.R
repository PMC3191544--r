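# Seeded generators for every input class the pipeline consumes, with
# ground-truth tables. All generators are pure functions of their
# parameters and seed.

# residues used at non-invariant template/backbone positions: no C or H,
# so planted zinc-finger spacings stay exact under mutation
.VAR_AA <- setdiff(AA20, c("C", "H"))

# Deterministic per-group/subgroup WRKY domain templates. The variable
# content is drawn once from a fixed internal stream, so the templates are
# constants of the package, independent of user seeds.
.wrkyTemplates <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(20110928L)
    rchars <- function(n) paste(sample(.VAR_AA, n, replace = TRUE),
                                collapse = "")
    c2h2 <- function() paste0("WRKYGQK", rchars(12), "C", rchars(4), "C",
                              rchars(22), "H", rchars(1), "H")
    c2hc <- function() paste0("WRKYGQK", rchars(12), "C", rchars(7), "C",
                              rchars(23), "H", rchars(1), "C")
    tpl <- list(`1N` = c2h2(), `1C` = c2h2(), `2a` = c2h2(),
                `2b` = c2h2(), `2c` = c2h2(), `2d` = c2h2(),
                `2e` = c2h2(), `3` = c2hc())
    cache <<- tpl
    tpl
  }
})

#' Planted WRKY domain templates
#'
#' The fixed domain templates used by [genProteome()]: one per group-1
#' terminal domain (1N, 1C), one per group-2 subgroup (2a-2e, C2H2
#' fingers) and one for group 3 (C2HC finger). Useful as seeds for
#' [iterativeSearch()].
#'
#' @param trim_to_common_length logical; trim all templates to the
#'   shortest template length so they form an aligned block.
#' @return named character vector of domain sequences.
#' @export
wrkyTemplateDomains <- function(trim_to_common_length = FALSE) {
  tpl <- unlist(.wrkyTemplates())
  if (trim_to_common_length) {
    L <- min(nchar(tpl))
    tpl <- vapply(tpl, substr, character(1), 1L, L)
  }
  tpl
}

# invariant positions of a template: signature + zinc-coordinating sites
.invariantPos <- function(tpl) {
  pos <- c(1:7)
  chars <- strsplit(tpl, "")[[1L]]
  c(pos, which(chars %in% c("C", "H")))
}

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  keep <- .invariantPos(seq)
  idx <- setdiff(seq_along(chars), keep)
  hit <- idx[runif(length(idx)) < rate]
  if (length(hit))
    chars[hit] <- sample(.VAR_AA, length(hit), replace = TRUE)
  paste(chars, collapse = "")
}

.randomBackbone <- function(n) {
  # W excluded so no spurious signature heptapeptide can arise
  paste(sample(setdiff(AA20, "W"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic proteome with planted WRKY proteins and decoys
#'
#' Family members embed the group templates in random backbone: group-1
#' proteins carry the 1N and 1C domains, group-2 subgroups and group 3 a
#' single domain. Point mutations at `mutation_rate` hit only
#' non-invariant positions (never the signature or the zinc-coordinating
#' residues). Half the decoys are plain random sequence; the other half
#' contain the signature but no resolvable zinc finger.
#'
#' @param group_counts named integer vector over
#'   c("1","2a","2b","2c","2d","2e","3"); the default mirrors a cucumber-
#'   sized family census (10, 4, 4, 16, 8, 7, 6 = 55 members).
#' @param n_decoys number of decoy proteins (default 90).
#' @param mutation_rate per-residue substitution probability at variable
#'   positions (default 0).
#' @param seed integer seed.
#' @param species id prefix (default "Cs").
#' @return list with `proteins` (named character vector), `truth`
#'   (data.frame: `protein_id`, `kind`, `group`, `subgroup`,
#'   `decoy_kind`), `params`, `seed`.
#' @export
genProteome <- function(group_counts = c(`1` = 10L, `2a` = 4L, `2b` = 4L,
                                         `2c` = 16L, `2d` = 8L, `2e` = 7L,
                                         `3` = 6L),
                        n_decoys = 90L, mutation_rate = 0,
                        seed = 1L, species = "Cs") {
  stopifnot(all(group_counts >= 0L), n_decoys >= 0L)
  set.seed(as.integer(seed))
  tpl <- .wrkyTemplates()
  proteins <- character(0)
  truth <- list()
  k <- 0L
  for (grp in names(group_counts)) {
    for (i in seq_len(group_counts[[grp]])) {
      k <- k + 1L
      id <- sprintf("%sWRKY%03d", species, k)
      if (grp == "1") {
        seqs <- paste0(.randomBackbone(30),
                       .mutate(tpl$`1N`, mutation_rate),
                       .randomBackbone(40),
                       .mutate(tpl$`1C`, mutation_rate),
                       .randomBackbone(30))
      } else {
        seqs <- paste0(.randomBackbone(50),
                       .mutate(tpl[[grp]], mutation_rate),
                       .randomBackbone(40))
      }
      proteins[id] <- seqs
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = id, kind = "family",
        group = if (grp %in% c("2a", "2b", "2c", "2d", "2e")) "2" else grp,
        subgroup = grp, decoy_kind = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_decoys)) {
    id <- sprintf("%sDECOY%03d", species, i)
    if (i %% 2L == 0L) {
      seqs <- .randomBackbone(200)               # no signature at all
      kind <- "random"
    } else {
      # signature present, but downstream window free of cysteines
      down <- paste(sample(setdiff(AA20, c("W", "C")), 120,
                           replace = TRUE), collapse = "")
      seqs <- paste0(.randomBackbone(60), "WRKYGQK", down)
      kind <- "signature_no_finger"
    }
    proteins[id] <- seqs
    truth[[length(truth) + 1L]] <- data.frame(
      protein_id = id, kind = "decoy", group = NA_character_,
      subgroup = NA_character_, decoy_kind = kind,
      stringsAsFactors = FALSE)
  }
  list(proteins = proteins, truth = do.call(rbind, truth),
       params = list(group_counts = group_counts, n_decoys = n_decoys,
                     mutation_rate = mutation_rate, species = species),
       seed = as.integer(seed))
}

#' Generate a synthetic qPCR Ct experiment
#'
#' A reference gene with constant baseline Ct plus Gaussian noise, and
#' target genes that are flat (null) or carry a planted induction bump:
#' per responsive (gene, stress), a log2 fold change at a random peak
#' timepoint, halved at the adjacent timepoints. Induction lowers the
#' target Ct by the log2 fold. Down-regulation occurs with probability
#' `p_down`.
#'
#' @param genes character vector of target gene ids.
#' @param stresses stress labels (default cold/salt/dry).
#' @param responsive_fraction probability a (gene, stress) is responsive.
#' @param log2_fold_range range the planted |log2 fold| is drawn from.
#' @param ct_noise_sd Gaussian Ct noise, cycles (default 0.2).
#' @param replicates biological replicates (default 3).
#' @param p_down probability a responsive effect is a repression.
#' @param seed integer seed.
#' @param reference_gene id of the reference gene (default "actin").
#' @return list with `ct` (data.frame: gene, stress, time_h, replicate,
#'   ct, is_reference), `truth` (gene, stress, responsive, log2_fold,
#'   peak_time_h), `params`, `seed`.
#' @export
genCtExperiment <- function(genes, stresses = STRESSES,
                            responsive_fraction = 0.5,
                            log2_fold_range = c(3, 4),
                            ct_noise_sd = 0.2, replicates = 3L,
                            p_down = 0.13, seed = 1L,
                            reference_gene = "actin") {
  stopifnot(responsive_fraction >= 0, responsive_fraction <= 1,
            replicates >= 1L)
  set.seed(as.integer(seed))
  times <- TIMEPOINTS_H
  rows <- list(); truth <- list()
  for (s in stresses) for (r in seq_len(replicates))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = reference_gene, stress = s, time_h = times, replicate = r,
      ct = 20 + rnorm(length(times), 0, ct_noise_sd),
      is_reference = TRUE, stringsAsFactors = FALSE)
  for (g in genes) for (s in stresses) {
    responsive <- runif(1) < responsive_fraction
    lfc <- 0; peak <- NA_real_
    bump <- numeric(length(times))
    if (responsive) {
      lfc <- runif(1, log2_fold_range[1L], log2_fold_range[2L])
      if (runif(1) < p_down) lfc <- -lfc
      pk <- sample(2:length(times), 1L)      # peak among 0.5..24 h
      peak <- times[pk]
      bump[pk] <- lfc
      if (pk > 2L) bump[pk - 1L] <- lfc / 2
      if (pk < length(times)) bump[pk + 1L] <- lfc / 2
    }
    for (r in seq_len(replicates))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, stress = s, time_h = times, replicate = r,
        ct = 24 - bump + rnorm(length(times), 0, ct_noise_sd),
        is_reference = FALSE, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      gene = g, stress = s, responsive = responsive, log2_fold = lfc,
      peak_time_h = peak, stringsAsFactors = FALSE)
  }
  list(ct = do.call(rbind, rows), truth = do.call(rbind, truth),
       params = list(responsive_fraction = responsive_fraction,
                     log2_fold_range = log2_fold_range,
                     ct_noise_sd = ct_noise_sd, replicates = replicates,
                     p_down = p_down),
       seed = as.integer(seed))
}

#' Generate paired cross-species expression profiles with a target
#' correlation
#'
#' For each ortholog pair and stress, log-responses at the six
#' post-treatment timepoints are drawn from a bivariate normal with
#' correlation `rho` and standard deviation `noise_sd`, exponentiated to
#' the ratio scale, and the 0 h value 1 is prepended.
#'
#' @param n_pairs number of ortholog pairs.
#' @param rho target log-scale correlation in [-1, 1].
#' @param noise_sd log-scale standard deviation (default 1).
#' @param stresses stress labels; each pair yields one dataset per
#'   stress.
#' @param seed integer seed.
#' @return list with `cs_profiles`, `at_profiles` (data.frames: gene,
#'   species, stress, t0, t0.5, t1, t3, t6, t12, t24), `pairs`
#'   (cs_gene, at_gene, stress), `truth` (rho per row of `pairs`),
#'   `params`, `seed`.
#' @export
genOrthologProfiles <- function(n_pairs, rho, noise_sd = 1,
                                stresses = STRESSES, seed = 1L) {
  stopifnot(rho >= -1, rho <= 1, n_pairs >= 1L)
  set.seed(as.integer(seed))
  ntp <- length(TIMEPOINTS_H) - 1L
  cs <- list(); at <- list(); pairs <- list()
  for (i in seq_len(n_pairs)) for (s in stresses) {
    z1 <- rnorm(ntp)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(ntp)
    v1 <- c(1, exp(noise_sd * z1))
    v2 <- c(1, exp(noise_sd * z2))
    csg <- sprintf("CsORTH%03d", i); atg <- sprintf("AtORTH%03d", i)
    cs[[length(cs) + 1L]] <- data.frame(
      gene = csg, species = "Cs", stress = s,
      t0 = v1[1], t0.5 = v1[2], t1 = v1[3], t3 = v1[4], t6 = v1[5],
      t12 = v1[6], t24 = v1[7], stringsAsFactors = FALSE)
    at[[length(at) + 1L]] <- data.frame(
      gene = atg, species = "At", stress = s,
      t0 = v2[1], t0.5 = v2[2], t1 = v2[3], t3 = v2[4], t6 = v2[5],
      t12 = v2[6], t24 = v2[7], stringsAsFactors = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      cs_gene = csg, at_gene = atg, stress = s, rho = rho,
      stringsAsFactors = FALSE)
  }
  list(cs_profiles = do.call(rbind, cs), at_profiles = do.call(rbind, at),
       pairs = do.call(rbind, pairs)[, 1:3],
       truth = do.call(rbind, pairs),
       params = list(n_pairs = n_pairs, rho = rho, noise_sd = noise_sd),
       seed = as.integer(seed))
}

#' Generate synthetic gene models with a conserved domain intron
#'
#' Each gene encodes a protein with a planted single-domain WRKY protein
#' whose domain carries an intron at the stated codon offset; intron
#' lengths are drawn around the species mean (5 percent coefficient of
#' variation, floored at 50 bp).
#'
#' @param n_genes genes per species.
#' @param intron_length_mean named numeric vector, mean intron length per
#'   species (e.g. `c(Cs = 686, At = 241)`).
#' @param conserved_intron_codon_offset 0-based codon offset of the intron
#'   within the domain (default 30).
#' @param seed integer seed.
#' @return list with per-species `models` (gene-model lists usable with
#'   [writeGeneModelsGff3()]), `proteins` (named character vector),
#'   `truth` (gene_id, species, intron_length, domain_start, domain_end,
#'   intron_codon_offset), `params`, `seed`.
#' @export
genGeneModels <- function(n_genes = 20L,
                          intron_length_mean = c(Cs = 686, At = 241),
                          conserved_intron_codon_offset = 30L,
                          seed = 1L) {
  tpl <- .wrkyTemplates()$`2c`
  dom_len <- nchar(tpl)
  if (conserved_intron_codon_offset < 0L ||
      conserved_intron_codon_offset > dom_len)
    stop("intron offset outside domain span")
  set.seed(as.integer(seed))
  flank <- 20L
  models <- list(); proteins <- character(0); truth <- list()
  for (sp in names(intron_length_mean)) {
    models[[sp]] <- list()
    for (i in seq_len(n_genes)) {
      prot <- paste0(.randomBackbone(flank), tpl, .randomBackbone(flank))
      id <- sprintf("%sGENE%03d", sp, i)
      proteins[id] <- prot
      L <- nchar(prot)
      cds_len <- 3L * L
      cut <- 3L * (flank + conserved_intron_codon_offset)
      ilen <- max(50L, as.integer(round(
        rnorm(1, intron_length_mean[[sp]],
              0.05 * intron_length_mean[[sp]]))))
      gstart <- (i - 1L) * 20000L
      models[[sp]][[id]] <- list(
        gene_id = id, chromosome = paste0(sp, "_chr1"), strand = "+",
        exons = data.frame(start = c(gstart, gstart + cut + ilen),
                           end = c(gstart + cut,
                                   gstart + cut + ilen + (cds_len - cut))))
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = id, species = sp, intron_length = ilen,
        domain_start = flank, domain_end = flank + dom_len,
        intron_codon_offset = conserved_intron_codon_offset,
        stringsAsFactors = FALSE)
    }
  }
  list(models = models, proteins = proteins,
       truth = do.call(rbind, truth),
       params = list(n_genes = n_genes,
                     intron_length_mean = intron_length_mean,
                     conserved_intron_codon_offset =
                       conserved_intron_codon_offset),
       seed = as.integer(seed))
}

#' Generate planted 1:1 ortholog domain sets for two species
#'
#' For each requested subgroup, member domains are drawn by mutating the
#' subgroup template at `member_noise` (paralog divergence); each member's
#' ortholog in the second species is derived from the member itself at the
#' smaller `ortholog_divergence`, so true pairs are mutually closest.
#' Group-1 members get separate N- and C-terminal domains.
#'
#' @param n_per_subgroup members per subgroup.
#' @param subgroups subset of c("1","2a","2b","2c","2d","2e","3").
#' @param member_noise per-residue mutation rate between family members.
#' @param ortholog_divergence per-residue mutation rate between orthologs.
#' @param seed integer seed.
#' @return list with `cs_domains`, `at_domains` (named character
#'   vectors; group-1 ids carry `_N`/`_C` suffixes), `pairs` (cs_id,
#'   at_id), `group_of` (named vector over cs ids), `seed`.
#' @export
genOrthologDomains <- function(n_per_subgroup = 2L,
                               subgroups = c("2a", "2b", "2c", "2d",
                                             "2e", "3"),
                               member_noise = 0.12,
                               ortholog_divergence = 0.02, seed = 1L) {
  set.seed(as.integer(seed))
  tpl <- .wrkyTemplates()
  cs <- character(0); at <- character(0)
  pairs <- list(); group_of <- character(0)
  k <- 0L
  for (sg in subgroups) for (i in seq_len(n_per_subgroup)) {
    k <- k + 1L
    cs_id <- sprintf("Cs%s_%02d", sg, i)
    at_id <- sprintf("At%s_%02d", sg, i)
    grp <- if (sg %in% c("2a", "2b", "2c", "2d", "2e")) "2" else sg
    group_of[cs_id] <- grp
    if (sg == "1") {
      for (tag in c("N", "C")) {
        m <- .mutate(tpl[[paste0("1", tag)]], member_noise)
        cs[paste0(cs_id, "_", tag)] <- m
        at[paste0(at_id, "_", tag)] <- .mutate(m, ortholog_divergence)
      }
    } else {
      m <- .mutate(tpl[[sg]], member_noise)
      cs[cs_id] <- m
      at[at_id] <- .mutate(m, ortholog_divergence)
    }
    pairs[[k]] <- data.frame(cs_id = cs_id, at_id = at_id,
                             stringsAsFactors = FALSE)
  }
  list(cs_domains = cs, at_domains = at,
       pairs = do.call(rbind, pairs), group_of = group_of,
       seed = as.integer(seed))
}
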