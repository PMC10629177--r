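Package: scLSTM
Title: Single-Cell Type Detection with a Siamese LSTM on Sigmoid-Kernel
    Similarities
Version: 0.1.0
Authors@R:
    person("scLSTM", "Developers", email = "sclstm@example.org",
           role = c("aut", "cre"))
Description: Detects cell types in single-cell RNA-seq expression matrices.
    Cells are embedded with an improved sigmoid kernel (log transform, row
    inner products, global min-max normalisation, hyperbolic tangent), a
    weight-sharing twin ("siamese") LSTM network is trained on same/different
    cell pairs to learn a pairwise similarity matrix, and cell types are
    assigned by agglomerative hierarchical clustering on the learned
    similarity. Includes k-means and spectral clustering variants, silhouette
    based estimation of the number of clusters, external validation metrics
    (NMI, Hungarian-mapped accuracy, adjusted Rand index, balanced accuracy),
    a negative-binomial synthetic scRNA-seq generator with marker genes and
    dropout, and readers for delimited and Matrix Market (10x-style)
    expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
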