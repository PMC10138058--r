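Package: censinar
Title: Bayesian Estimation for Censored Count Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and Bayesian estimation of first-order convolution-closed
    infinitely-divisible (CCID(1)) count time series observed under a known
    exogenous (type-1) detection limit. Provides simulators and transition
    probabilities for the Poisson, negative binomial and generalised Poisson
    INAR(1) families, exact right/left censoring of latent paths, rejection
    Approximate Bayesian Computation with variance-scaled summary statistics,
    and a Gibbs sampler with data augmentation in which limit observations are
    imputed by the median of multiple draws from the truncated marginal
    (GDA-MMS). Censoring-blind conditional least squares, conditional maximum
    likelihood and Gibbs baselines quantify the bias of ignoring the limit,
    and a scenario harness reproduces the accompanying simulation study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
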