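Package: cadet
Title: Correspondence Analysis for Dimension Reduction of Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correspondence analysis (CA) and overdispersion-adapted variants
    for dimension reduction of feature-by-cell count matrices, such as
    single-cell RNA-seq data. Implements SVD of Pearson, Freeman-Tukey, and
    indexed chi-squared residuals, optional variance-stabilizing count
    transformations (square root, Anscombe, Freeman-Tukey) and power
    deflation smoothing, standard and principal coordinate scores, biplot
    preparation, and elbow-based component selection. Includes a multi-table
    joint embedding across batches via per-table residual scaling and a
    single SVD, a scaled-variance metric for batch integration, adjusted
    Rand index evaluation, a gamma-Poisson synthetic count generator with
    cluster structure and batch effects, Matrix Market and delimited-text
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    mclust,
    methods,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
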