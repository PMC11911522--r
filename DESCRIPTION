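Package: simplexDeconv
Title: Reference-Free Deconvolution of Spatial Transcriptomics by
    Minimum-Volume Simplex Identification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-spot cell-type proportions and per-type
    expression profiles from spatial transcriptomics count matrices
    without a single-cell reference. The pipeline selects the number of
    cell types by a corrected AIC over alternating constrained
    least-squares factorizations, iteratively selects cell-type-specific
    genes, identifies the corners of the data simplex with a split
    augmented Lagrangian (SISAL-style) minimum-volume solver, rescales
    the recovered corners into column-stochastic proportions, and ranks
    marker genes by corner proximity. Includes a spot-mixture simulator
    with region-dominant cell types and a heterogeneity rate, evaluation
    metrics (RMSE, MAE, JSD, PCC) with cell-type alignment, and
    data-driven cell-type label assignment against an annotated
    reference panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    e1071,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, Spatial, GeneExpression, CellBiology,
    DimensionReduction
RoxygenNote: 7.3.3
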