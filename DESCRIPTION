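Package: ensembleGP
Title: Ensembles of Diverse Genomic Prediction Models with Diversity Decomposition
Version: 0.1.0
Authors@R:
    person("Queensland", "Breeding Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying naive ensemble
    averaging of genomic prediction models in biparental recombinant inbred
    line (RIL) populations. Simulates BC1S4 RIL populations with known trait
    architectures, implements the standard genomic data-cleaning chain
    (missing-call imputation, SNP missingness filtering, windowed LD pruning,
    environment concatenation, randomized splits), provides six predictors
    under one fit/predict contract (rrBLUP, BayesB, Gaussian-kernel RKHS,
    random forest, epsilon-SVR, and a star-graph attention network), combines
    them by equal-weight averaging, decomposes squared error into ensemble
    error, average error and prediction diversity, and attributes per-marker
    effects via coefficients, Shapley values, impurity importance and
    integrated gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
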