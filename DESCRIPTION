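Package: frusc
Title: Single-Cell Atlas and Activity-Monitor Analysis of fruitless-Expressing Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for droplet single-cell RNA-seq atlases of
    Drosophila fruitless (fru P1) neurons and for the locomotor-activity
    follow-up experiments such atlases motivate. Covers cell-level quality
    control, log-normalization, highly variable gene selection, jackstraw
    principal-component significance, shared-nearest-neighbor graph
    clustering, Wilcoxon rank-sum marker and sex-differential expression
    testing, sex-bias classification of cluster composition, declarative
    marker-gene cluster annotation, gene-gene co-expression statistics,
    downsampling robustness analyses with correlation-based cluster matching,
    and targeted subclustering. A companion module analyzes per-fly
    minute-binned beam-crossing traces: dead-fly filtering, sleep-bout
    detection, and chi-square (Sokolove-Bushell) periodogram estimation of
    circadian period. A synthetic-data module generates count matrices and
    activity traces with planted ground truth so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    RANN,
    uwot,
    irlba,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
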