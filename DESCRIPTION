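Package: spikeconn
Title: Directed Functional Connectivity from Spike Trains via Regularized
    GLMs and Empirical Bayesian Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates directed functional connectivity between neurons from
    binned binary spike trains. Spike response functions are modelled as linear
    combinations of Gamma-density smooth bases inside a Bernoulli generalized
    linear model (logistic or complementary log-log link) fitted by maximizing
    an L2-, L1- or group-lasso-regularized log-likelihood. Connection
    significance is assessed by likelihood-ratio (Granger-type) tests with
    chi-square or empirically refitted degrees of freedom, and by an empirical
    Bayesian procedure that estimates q values and local false discovery rates
    directly from surrogate (time-shifted) neuron null statistics. Includes
    estimation of common external input channels by smoothing and principal
    component analysis with AIC model selection, recurrent GLM network
    simulators for benchmarking, and ROC/AUC and false-discovery-proportion
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
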