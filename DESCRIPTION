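Package: epimcc
Title: Spatial and Single-Cell Analysis of Epidermotropic Merkel Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare epidermotropic, tumor-core and perivascular
    Merkel cell carcinoma (MCC) cells from high-definition spatial
    transcriptomics and independent single-cell RNA-seq. Implements
    bin-to-cell reconstruction of 2 micrometre binned counts by nuclear
    label expansion and aggregation, region-based cell selection,
    keratin-excluded pooled principal component analysis with multivariate-t
    confidence ellipses, rank-based enrichment of marker panels among PC
    loadings, zero-preserving low-rank imputation, AUCell-style gene-set
    activity with regulon specificity scores, rule-based subtype gating with
    balanced subsampling and rank-sum differential expression, and a
    synthetic tissue and count generator with known ground truth so that
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    ggplot2,
    methods,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
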