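Package: cardioqtl
Title: Case/Control Cardiac Transcriptome Genetics Toolkit
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical procedures for case/control transcriptome-genetics
    studies of the heart: differential expression (Wilcoxon with a fold-change
    gate), percent-spliced-in differential exon usage with a power/FDR
    simulation engine, cis-eQTL and condition-specific eQTL mapping,
    splicing-QTL testing via an exon-by-genotype interaction model,
    allele-specific expression with resampled binomial tests, LD-block GWA
    enrichment, SNP functional-annotation enrichment, and an L1-regularized
    multilocus risk score with nested cross-validation. Includes a synthetic
    cohort generator that emulates the assumed data structure so every stage
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
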