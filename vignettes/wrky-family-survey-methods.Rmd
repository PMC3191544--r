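---
title: "Methods: a genome-wide survey toolkit for the WRKY family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide survey toolkit for the WRKY family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkysurvey)
```

## Scope

WRKY proteins are one of the largest plant transcription-factor families.
A member is defined by the ~60-residue WRKY domain: the invariant
heptapeptide `WRKYGQK` followed by a zinc-finger motif. Two finger
chemistries occur — C2H2 (`C-x4..5-C-x21..23-H-x1-H`) and C2HC
(`C-x5..8-C-x23..28-H-x1..2-C`) — and the family splits into group 1
(two C2H2 domains), group 2 (one C2H2 domain, phylogenetic subgroups
2a–2e) and group 3 (one C2HC domain).

`wrkysurvey` packages the full analysis chain of a genome-wide family
survey: domain scanning and group classification, an iterative profile
search, NJ phylogenies with bootstrap supports and reference-clade
subgroup assignment, ortholog calling, ΔΔCt expression quantification,
cross-species expression-conservation statistics, a positive-selection
decision layer over externally fitted codon models, and gene-structure
utilities. Seeded generators produce synthetic inputs with ground-truth
tables for every stage.

## Domain scanning

`scanDomains()` reports a domain for every `WRKYGQK` occurrence that has
a resolvable zinc finger within a 90-residue window downstream. The
C2H2 pattern is tried before C2HC, with lazy quantifiers so the leftmost,
shortest-gap finger is reported. Coordinates are 0-based half-open
internally; all written tables are 1-based inclusive (BED output keeps
the BED convention). Spacing ranges and the window are configuration
(`zincFingerConfig()`), not constants, because family surveys in
different genomes routinely need to widen them.

`classifyGroup()` turns the domain complement into group calls
(2 × C2H2 → 1, 1 × C2H2 → 2, 1 × C2HC → 3); anything else is
`unclassified` with the triggering evidence recorded rather than guessed.

## Iterative profile search

Surveys bootstrap their family lists by re-searching the proteome with a
profile built from the members already found. `buildPssm()` uses
log-odds scores `log2((count + pc·bg) / (n + pc) / bg)` with pseudocount
`pc = 0.05` and a uniform background; columns with more than 50% gaps are
dropped. The membership threshold is 0.6 of the maximum attainable
window score — a fraction of the profile optimum rather than an absolute
score so the threshold tracks profile length. `iterativeSearch()` admits
proteins at or above threshold, rebuilds the profile from members' best
windows, and iterates; membership is monotone non-decreasing, so the
fixpoint exists and the search terminates.

## Phylogeny and subgroup assignment

Multiple alignment uses the classic center-star construction over
Biostrings global alignments (BLOSUM62, gap open 10, extend 1) with
"once a gap, always a gap" merging — adequate for blocks of homologous
~60-residue domains and fully deterministic. Distances are p-distances
with pairwise gap deletion (`poissonCorrect()` optional), trees are
neighbor-joining (`ape::nj`) with negative branch estimates clamped to 0,
and supports come from seeded column-resampling bootstrap
(`bootstrapSupport()`). `assignSubgroup()` places each query by the
smallest clade with support ≥ 50 containing reference leaves of exactly
one subgroup; clades mixing reference subgroups leave the query
unclassified rather than forcing a call.

## Ortholog calling

`cladeCandidates()` emits cross-species pairs inside minimal clades whose
support strictly exceeds 50. `bbhPairs()` (bidirectional best hits)
corroborates; it is recorded as a flag rather than used as a veto because
reciprocal-best-hit lists are incomplete under lineage-specific
duplication (a `require_bbh` switch makes it a hard filter). Group-1
proteins have two domains, so `callOrthologs()` additionally requires the
same pairing to be recovered in both the N-terminal and the C-terminal
domain trees, and accepts a manual veto list for curatorial exclusions.

## Expression quantification

`relativeExpression()` implements ΔΔCt: per replicate,
ΔCt = Ct(target) − Ct(reference); ΔΔCt subtracts the same replicate's
0 h ΔCt of the same stress; the relative amount is the replicate mean of
2^−ΔΔCt. `callDifferential()` tests each post-treatment timepoint
against 0 h with a two-sided pooled-variance Student t-test on the
replicate ΔCt values (the classical design for three biological
replicates), calls a gene responsive at p < 0.01, and splits "+"
from "++" at |log2 fold| ≥ 3. The tier threshold is configuration:
published call tables rarely quantify their legend, so the packaged
stress-call fixture is treated as labels, not recomputed.

## Expression conservation

`pairCorrelation()` is the sample Pearson correlation across the seven
timepoints (0, 0.5, 1, 3, 6, 12, 24 h), computed on the ratio scale with
the 0 h point included by default — matching how relative-expression
series are usually reported. Both series equal 1 at 0 h by construction,
and this shared anchor gives even independent series a small positive
expected correlation; the package therefore judges ortholog correlations
against `randomPairNull()` — random stress-matched cross-species pairs
drawn from the same pools, which carry the same anchor — rather than
against zero. `compareToNull()` uses a Welch t-test (unequal sample
sizes and variances). A `log_scale` flag and an `include_zero` switch
expose the alternative conventions.

## Positive selection

The codon-model fits (M0/M3/M7/M8) come from external software; the
package owns only the decision layer. `lrt()` compares 2ΔlnL with a
chi-square upper tail (df 4 for M3 vs M0, df 2 for M8 vs M7 — where the
p-value is exactly `exp(−x/2)`), starring p < 0.05 and p < 0.01.
`positiveSelectionCall()` requires all three of: M8 selected-class ω
strictly above 1, at least one Bayes-Empirical-Bayes site, and a
significant M8-vs-M7 test.

## Gene structure

`assignNames()` numbers genes along chromosomes, appending unplaced loci
by search score; `tandemArrays()` reports runs of neighbours within
50 kb; `mapDomainIntrons()` maps introns onto the domain's codon span
(an intron exactly at the domain start is outside, by the half-open
convention). A minimal gene/mRNA/CDS GFF3 dialect round-trips the gene
models.

## Synthetic data: realism and limits

The generators are study conditions, not tuning knobs. Domain templates
are fixed package constants; mutation never touches the signature or the
zinc-coordinating residues, and random backbone excludes tryptophan, so
planted families are exactly recoverable at zero noise and degrade
gracefully with `mutation_rate`. Decoys are either pure backbone or
signature-bearing sequences with a cysteine-free downstream window.
Limits worth knowing: synthetic proteins are far shorter than real ones;
Ct noise is Gaussian and homoscedastic; expression profiles are
log-normal around a bivariate-normal log-correlation `rho`, so the
ratio-scale Pearson r is an attenuated estimate of `rho`; gene models
have exactly one intron. These simplifications keep every ground truth
exact while preserving the statistical structure each stage is meant to
detect.

## A worked example

```{r example, eval = FALSE}
p <- genProteome(mutation_rate = 0.05, seed = 7)
scan <- scanProteome(p$proteins)
scan
table(groupCalls(scan)$group)

report <- runPipeline(wrkyPipelineConfig(mode = "fixtures"))
str(report$fixtures)
```

`runPipeline()` at a fixed seed is deterministic end to end: rerunning
writes a byte-identical report bundle.
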