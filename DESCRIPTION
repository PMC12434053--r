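Package: netsdecon
Title: Cell-Type-Resolved Deconvolution and Expression Analysis of Sorted
    Brain Nuclei RNA-seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signature-based analysis of nuclear RNA-seq from sorted and
    unsorted brain cell populations. Provides simplex-constrained global
    deconvolution of unsorted samples against sorted reference signatures,
    the comparative (target-versus-rest) two-signature deconvolution used
    to contrast cell-type composition between disease conditions,
    specificity-index marker discovery with tertile stratification and
    contamination scoring, a simplified covariate-aware linear-model
    differential-expression stage with residual-PCA hidden covariates,
    preranked gene-set enrichment analysis and gene-set scoring, a
    transcriptomic age axis, and a negative-binomial synthetic cohort
    generator with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
biocViews: GeneExpression, RNASeq, Transcriptomics, CellBiology, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
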