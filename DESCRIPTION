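Package: wrkysurvey
Title: Genome-Wide Survey Toolkit for the WRKY Transcription-Factor Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide surveys of the plant WRKY
    transcription-factor family: detection of WRKY signature domains and
    their C2H2/C2HC zinc fingers in proteomes, group (1, 2a-2e, 3)
    classification, iterative profile (PSSM) family search, neighbor-joining
    phylogenies with bootstrap support and reference-clade subgroup
    assignment, combined phylogeny/bidirectional-best-hit ortholog calling,
    qPCR delta-delta-Ct relative expression with differential calls,
    cross-species ortholog expression-conservation statistics against a
    randomized-pair null, a likelihood-ratio-test decision layer for
    positive selection over codon-model fits, chromosome-order gene naming,
    tandem-array detection and domain-relative intron mapping. Ships seeded
    synthetic-data generators with ground-truth tables so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
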