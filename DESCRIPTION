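Package: scirt
Title: Iterative Dropout Imputation and Dimensionality Reduction for
    Single-Cell RNA-Seq via Ensemble Ranks, Randomly Weighted Blending and
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes dropout zeros in single-cell RNA-seq expression
    matrices with a multi-layer scheme: cell-cell similarity is obtained by
    rank-aggregating an ensemble of distance metrics, each cell is updated
    as a convex blend of itself and similar cells using geometric-
    distribution random weights (a SMOTE-style update), and every layer's
    result is denoised by a rank-k non-negative matrix factorization
    (Lee-Seung multiplicative updates under Gaussian or Poisson noise).
    A final factorization yields both the imputed high-dimensional
    expression matrix and a low-dimensional cell representation for
    clustering. Includes a negative-binomial cluster-structured count
    simulator with an exact-count dropout masking protocol, and clustering
    evaluation metrics (ARI, NMI, silhouette, Davies-Bouldin, flattened-
    matrix Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    generics,
    tibble,
    rlang,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
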