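# Pipeline orchestration: run the survey stages over packaged fixtures
# and/or synthetic data, and emit a deterministic report bundle.

#' Pipeline configuration
#'
#' A flat key-value configuration covering every stage threshold. All
#' randomness flows from the single `seed`, split internally per stage.
#'
#' @param mode "fixtures" (packaged census tables only), "synthetic"
#'   (generators end to end), or "both".
#' @param seed root integer seed.
#' @param stages character subset of
#'   c("scan", "phylo", "ortho", "expr", "cons", "select", "struct").
#' @param mutation_rate proteome generator noise (synthetic mode).
#' @param n_decoys decoys in the synthetic proteome.
#' @param support_threshold bootstrap support cutoff for ortholog calls
#'   (strict) and subgroup assignment.
#' @param bootstrap_n bootstrap replicates for synthetic trees.
#' @param alpha qPCR differential-call significance level.
#' @param tier_log2 fold tier split (|log2 fold|) for "++"/"--" calls.
#' @param n_expr_genes synthetic qPCR target genes.
#' @param n_pairs synthetic ortholog-profile pairs.
#' @param rho target log-scale correlation of synthetic ortholog pairs.
#' @param null_n random pairs in the conservation null.
#' @param selection_alpha LRT significance level for the selection
#'   verdict.
#' @param n_struct_genes synthetic gene models per species.
#' @return named list.
#' @export
wrkyPipelineConfig <- function(mode = c("both", "fixtures", "synthetic"),
                               seed = 1L,
                               stages = c("scan", "phylo", "ortho",
                                          "expr", "cons", "select",
                                          "struct"),
                               mutation_rate = 0.05,
                               n_decoys = 90L,
                               support_threshold = 50,
                               bootstrap_n = 100L,
                               alpha = 0.01,
                               tier_log2 = 3,
                               n_expr_genes = 10L,
                               n_pairs = 8L,
                               rho = 0.4,
                               null_n = 100L,
                               selection_alpha = 0.05,
                               n_struct_genes = 20L) {
  list(mode = match.arg(mode), seed = as.integer(seed), stages = stages,
       mutation_rate = mutation_rate, n_decoys = n_decoys,
       support_threshold = support_threshold,
       bootstrap_n = as.integer(bootstrap_n), alpha = alpha,
       tier_log2 = tier_log2, n_expr_genes = as.integer(n_expr_genes),
       n_pairs = as.integer(n_pairs), rho = rho,
       null_n = as.integer(null_n), selection_alpha = selection_alpha,
       n_struct_genes = as.integer(n_struct_genes))
}

# stage seeds derived deterministically from the root seed
.stageSeed <- function(seed, stage) {
  offs <- c(scan = 11L, phylo = 23L, ortho = 37L, expr = 41L,
            cons = 53L, struct = 67L)
  (as.integer(seed) * 101L + offs[[stage]]) %% 2147483629L
}

#' Run the survey pipeline
#'
#' Executes the configured stages over the packaged fixtures and/or
#' synthetic data and (optionally) writes the report bundle. The summary
#' collects the family census, ortholog-conservation statistics and
#' selection verdicts.
#'
#' @param config from [wrkyPipelineConfig()].
#' @param out_dir optional output directory; created if missing. When
#'   given, stage tables and `summary.json` are written via
#'   [makeReport()].
#' @return the summary list, invisibly carrying the stage outputs in
#'   attribute "details".
#' @export
runPipeline <- function(config = wrkyPipelineConfig(), out_dir = NULL) {
  summary <- list(seed = config$seed, mode = config$mode)
  details <- list()
  fixtures <- config$mode %in% c("fixtures", "both")
  synthetic <- config$mode %in% c("synthetic", "both")

  if (fixtures) {
    fam <- summarizeFamilyTables()
    t3 <- table3Summary()
    summary$fixtures <- list(
      n_expressed = fam$n_expressed,
      n_est_supported = fam$n_est_supported,
      n_responsive = fam$n_responsive,
      n_datasets = t3$n_datasets,
      n_cs_genes = t3$n_cs_genes,
      mean_ortholog_r = t3$mean_r,
      n_gt_0.5 = t3$n_gt_0.5)
    if ("select" %in% config$stages) {
      sel <- selectionTable(wrkyFixture("selection_lrt"),
                            alpha = config$selection_alpha)
      summary$fixtures$n_positive_at <-
        sum(sel$positive_selection[sel$species == "AtWRKY"])
      summary$fixtures$n_positive_cs <-
        sum(sel$positive_selection[sel$species == "CsWRKY"])
      details$selection <- sel
    }
  }

  if (synthetic) {
    syn <- list()
    if ("scan" %in% config$stages) {
      prot <- genProteome(mutation_rate = config$mutation_rate,
                          n_decoys = config$n_decoys,
                          seed = .stageSeed(config$seed, "scan"))
      scan <- scanProteome(prot$proteins)
      calls <- groupCalls(scan)
      fam_truth <- prot$truth[prot$truth$kind == "family", ]
      found <- calls$protein_id[calls$group != "unclassified"]
      syn$family_size <- length(found)
      syn$family_recall <- mean(fam_truth$protein_id %in% found)
      syn$family_precision <- mean(found %in% fam_truth$protein_id)
      syn$census <- as.list(table(calls$group[calls$group !=
                                                "unclassified"]))
      details$scan <- scan; details$proteome <- prot
    }
    if ("phylo" %in% config$stages && !is.null(details$scan)) {
      d <- domainTable(details$scan)
      g <- groupCalls(details$scan)
      single <- d[d$terminal_tag == "only", ]
      doms <- setNames(
        substr(as.character(proteome(details$scan)[single$protein_id]),
               single$domain_start + 1L, single$domain_end),
        single$protein_id)
      refs <- wrkyReferencePanel()
      ref_map <- setNames(names(.wrkyTemplates()), c("1", "1", "2a",
                                                     "2b", "2c", "2d",
                                                     "2e", "3"))
      ref_doms <- setNames(
        unlist(.wrkyTemplates())[ref_map[refs]], names(refs))
      msa <- centerStarMsa(c(doms, ref_doms))
      rows <- setNames(msa$rows, msa$ids)
      tree <- bootstrapSupport(rows, n_reps = config$bootstrap_n,
                               seed = .stageSeed(config$seed, "phylo"))
      sub <- assignSubgroup(tree, refs,
                            threshold = config$support_threshold)
      truth_sub <- details$proteome$truth
      truth_sub <- setNames(truth_sub$subgroup, truth_sub$protein_id)
      g2 <- names(sub)[g$group[match(names(sub), g$protein_id)] == "2"]
      syn$subgroup_accuracy <- mean(sub[g2] == truth_sub[g2])
      details$tree <- tree; details$subgroups <- sub
    }
    if ("ortho" %in% config$stages) {
      od <- genOrthologDomains(n_per_subgroup = 2L,
                               seed = .stageSeed(config$seed, "ortho"))
      res <- syntheticOrthologAnalysis(od,
                                       threshold =
                                         config$support_threshold,
                                       bootstrap_n = config$bootstrap_n,
                                       seed = .stageSeed(config$seed,
                                                         "ortho"))
      syn$n_orthologs <- nrow(res$orthologs)
      syn$ortholog_recall <- res$recall
      syn$ortholog_precision <- res$precision
      details$orthologs <- res$orthologs
    }
    if ("expr" %in% config$stages) {
      ctx <- genCtExperiment(sprintf("G%02d", seq_len(config$n_expr_genes)),
                             seed = .stageSeed(config$seed, "expr"))
      rel <- relativeExpression(ctx$ct)
      calls <- callDifferential(rel, alpha = config$alpha,
                                tier_log2 = config$tier_log2)
      responsive <- apply(calls[, -1L, drop = FALSE] != "nc", 1, any)
      syn$n_responsive <- sum(responsive)
      truth_resp <- tapply(ctx$truth$responsive, ctx$truth$gene, any)
      syn$responsive_accuracy <-
        mean(responsive == truth_resp[calls$gene])
      details$expression <- list(rel = rel, calls = calls, truth = ctx$truth)
    }
    if ("cons" %in% config$stages) {
      op <- genOrthologProfiles(n_pairs = config$n_pairs, rho = config$rho,
                                seed = .stageSeed(config$seed, "cons"))
      orth <- orthologCorrelations(op$pairs, op$cs_profiles,
                                   op$at_profiles)
      null <- randomPairNull(op$cs_profiles, op$at_profiles,
                             n = config$null_n,
                             seed = .stageSeed(config$seed, "cons") + 1L)
      cmp <- compareToNull(orth$r, null)
      syn$mean_ortholog_r <- cmp$mean_ortholog_r
      syn$mean_null_r <- cmp$mean_null_r
      syn$conservation_p <- cmp$p_value
      details$conservation <- list(orth = orth, null = null, cmp = cmp)
    }
    if ("struct" %in% config$stages) {
      gm <- genGeneModels(n_genes = config$n_struct_genes,
                          seed = .stageSeed(config$seed, "struct"))
      stats <- lapply(split(gm$truth, gm$truth$species), function(tt) {
        pooled <- do.call(rbind, lapply(tt$gene_id, function(id) {
          sp <- tt$species[tt$gene_id == id]
          m <- gm$models[[sp]][[id]]
          mapDomainIntrons(m$exons, m$strand,
                           tt$domain_start[tt$gene_id == id],
                           tt$domain_end[tt$gene_id == id])
        }))
        domainIntronStats(pooled)
      })
      if (all(c("Cs", "At") %in% names(stats)))
        syn$intron_length_ratio <-
          round(stats$Cs$mean_bp / stats$At$mean_bp, 1)
      syn$intron_stats <- stats
      details$gene_models <- gm
    }
    summary$synthetic <- syn
  }

  if (!is.null(out_dir)) makeReport(summary, details, out_dir)
  attr(summary, "details") <- details
  invisible(summary)
}

#' Ortholog calling over a planted domain set
#'
#' Builds the bootstrap NJ tree of the pooled two-species domains, calls
#' supported cross-species clade candidates, computes BBH corroboration
#' from pairwise alignment scores, applies the N/C congruence rule for
#' group-1 members, and scores recovery against the planted pairs.
#'
#' @param od output of [genOrthologDomains()].
#' @param threshold support cutoff (strict).
#' @param bootstrap_n bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return list with `orthologs` (from [callOrthologs()]), `recall`,
#'   `precision`, `tree`.
#' @export
syntheticOrthologAnalysis <- function(od, threshold = 50,
                                      bootstrap_n = 100L, seed = 1L) {
  # group-1 proteins enter the main tree via their C-terminal domain
  pick <- function(doms) {
    cc <- doms[grepl("_C$", names(doms))]
    names(cc) <- sub("_C$", "", names(cc))
    c(doms[!grepl("_[NC]$", names(doms))], cc)
  }
  cs_single <- pick(od$cs_domains)
  at_single <- pick(od$at_domains)
  g1 <- grepl("_[NC]$", names(od$cs_domains))
  all_doms <- c(cs_single, at_single)
  msa <- centerStarMsa(all_doms)
  tree <- bootstrapSupport(setNames(msa$rows, msa$ids),
                           n_reps = bootstrap_n, seed = seed)
  species_of <- setNames(ifelse(names(all_doms) %in% names(cs_single),
                                "cs", "at"), names(all_doms))
  cand <- cladeCandidates(tree, species_of, threshold)
  scores <- matrix(NA_real_, length(cs_single), length(at_single),
                   dimnames = list(names(cs_single), names(at_single)))
  for (a in names(cs_single)) for (b in names(at_single))
    scores[a, b] <- pairwiseAlignScore(cs_single[[a]],
                                       at_single[[b]])$score
  bbh <- bbhPairs(scores)
  nc_trees <- NULL
  if (any(g1)) {
    nc_trees <- lapply(c(N = "N", C = "C"), function(tag) {
      dd <- c(od$cs_domains[grepl(paste0("_", tag, "$"),
                                  names(od$cs_domains))],
              od$at_domains[grepl(paste0("_", tag, "$"),
                                  names(od$at_domains))])
      names(dd) <- sub(paste0("_", tag, "$"), "", names(dd))
      m <- centerStarMsa(dd)
      bootstrapSupport(setNames(m$rows, m$ids), n_reps = bootstrap_n,
                       seed = seed + 1L)
    })
  }
  orth <- callOrthologs(cand, bbh, od$group_of, nc_trees, threshold)
  truth_keys <- paste(od$pairs$cs_id, od$pairs$at_id)
  call_keys <- paste(orth$cs_id, orth$at_id)
  list(orthologs = orth,
       recall = mean(truth_keys %in% call_keys),
       precision = if (length(call_keys))
         mean(call_keys %in% truth_keys) else NA_real_,
       tree = tree)
}

#' Write the report bundle
#'
#' Deterministic file set: stage TSVs plus `summary.json` (stamped with
#' the package version and root seed). Re-running on the same inputs
#' reproduces the bundle byte for byte.
#'
#' @param summary,details as produced inside [runPipeline()].
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
makeReport <- function(summary, details, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(details$selection))
    wr(details$selection, "selection_verdicts.tsv")
  if (!is.null(details$orthologs))
    wr(details$orthologs, "ortholog_pairs.tsv")
  if (!is.null(details$expression))
    wr(details$expression$calls, "stress_calls.tsv")
  if (!is.null(details$conservation))
    wr(details$conservation$orth, "ortholog_correlations.tsv")
  if (!is.null(details$scan))
    wr(domainTable(details$scan), "domains.tsv")
  summary$package_version <- as.character(packageVersion("wrkysurvey"))
  p <- file.path(out_dir, "summary.json")
  write_json(summary, p, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
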