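Package: smssvd
Title: SubMatrix Selection Singular Value Decomposition
Version: 0.1.0
Authors@R:
    person("SMSSVD", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parameter-free unsupervised signal decomposition for
    variables-by-samples data matrices (P >> N omics matrices in
    particular). Each signal is found by optimizing the projection score
    of variance-filtered variable subsets against a within-variable
    permutation null, extracting a truncated SVD of the selected
    submatrix, expanding it back to all variables through the SVD of the
    data matrix restricted to the selected right-singular subspace, and
    deflating before the next iteration. The result is a denoised,
    orthogonal, SVD-like decomposition. Includes a synthetic benchmark
    generator with orthogonal sparse-support low-rank signals, a
    support-restricted reconstruction-error metric with greedy component
    matching, Gaussian-mixture AIC model scoring, and delimited-text /
    MatrixMarket input-output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
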