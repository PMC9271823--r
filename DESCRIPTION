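Package: cardiomap
Title: Cross-Species Comparison of Human and Mouse Embryonic Heart
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing single-cell transcriptomes of
    developing hearts across species: per-cell quality control with
    species-specific presets, artificial-nearest-neighbor doublet detection,
    log-normalization, highly variable gene selection, PCA, geometric
    sketching for platform balancing, iterative centroid batch alignment,
    kNN-graph modularity clustering, one-vs-rest rank-sum marker detection,
    marker-dictionary cell-type annotation, one-to-one ortholog pseudobulk
    correlation, centroid-MST pseudotime with negative-binomial spline tests
    and three-phase gene clustering, hypergeometric over-representation, and
    a PC1 density procedure that maps mouse developmental stages onto human
    stages. Ships a two-species synthetic data generator with ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
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
    irlba,
    RANN,
    MASS,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
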