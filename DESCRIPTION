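Package: fatesimplex
Title: Three-Fate Simplex Mapping and Velocity-Derived Differentiation
    Potential for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects single cells (transcriptomic or chromatin-accessibility
    profiles) onto a three-fate barycentric simplex by averaging Euclidean
    distances to three terminal "apex" clusters, transforming and
    renormalizing the resulting similarities, and overlays a future
    differentiation potential derived from a steady-state RNA-velocity
    graph, averaged per apex cluster and drawn as binned arrow fields.
    Includes the supporting preprocessing stages (count filtering,
    median-total normalization, variable-feature selection, non-centered
    scaling, ATAC gene-activity counting, PCA/KNN graph construction),
    one-vs-rest Wilcoxon rank-sum marker selection with Benjamini-Hochberg
    adjustment, and a negative-binomial synthetic-data generator with known
    three-fate ground truth so every stage is verifiable without external
    data.
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
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
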