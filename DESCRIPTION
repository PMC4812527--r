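Package: envmeth
Title: Separating Environment- from Genotype-Associated Differential DNA
    Methylation in Whole-Genome Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated re-implementation of a smoothing-based pipeline for
    calling differentially methylated regions (DMRs) from whole-genome
    bisulfite sequencing count data in an exposed-versus-unexposed cohort
    design, and for dissecting the calls downstream: local-likelihood
    methylation smoothing with SAM-style moderated testing and
    permutation-based false discovery rate estimation; methylation-QTL
    classification of DMRs into genotype-influenced (gDMR) and
    non-genetically-influenced (ngDMR) classes, including CpG-destroying
    variants; longitudinal stability classification of DMRs across
    timepoints; 16-state Bernoulli-emission hidden Markov model chromatin
    segmentation from four binarized histone-mark tracks with group
    consensus and condition-transition analysis; shuffle-based enrichment of
    DMRs in chromatin element classes; commuting-enhancer classification
    from enhancer-gene interaction data; and methylation-expression
    coupling by chromatin category. A seeded synthetic-data generator
    produces complete inputs with the statistical structure the analysis
    assumes, so every stage is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
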