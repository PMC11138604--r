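Package: plsbd
Title: Change-Point Detection with a Pearson-Like Scaled Bregman Divergence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Offline change-point detection in multivariate time series by
    density-ratio estimation. Implements the Pearson-like scaled Bregman
    divergence, a bounded two-sample dissimilarity built from the relative
    density ratio under a mixture reference measure, estimated with a
    Gaussian-kernel ridge regression model whose bandwidth and
    regularization are selected by cross-validation. Provides a
    sliding-window detector with percentile thresholding, least-squares
    importance-fitting baselines (uLSIF and RuLSIF scores), a random
    covariate-subsampling ensemble for high-dimensional (omics-style)
    matrices, seeded synthetic benchmark generators, candidate/ground-truth
    matching utilities, CSV/TSV readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
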