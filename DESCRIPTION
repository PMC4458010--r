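Package: crtddf
Title: Small-Sample Wald F Inference for Cluster-Randomized Trials with
    Binary Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the random-intercept logistic generalized linear mixed
    model by penalized quasi-likelihood (pseudo-likelihood) with REML
    estimation of the variance components on the working linear mixed
    model, and tests the intervention effect in two-arm cluster-randomized
    trials with a Wald F statistic under five denominator-degrees-of-freedom
    approximations: Residual, Containment, Between-Within, Satterthwaite
    (multivariate delta method) and Kenward-Roger (small-sample covariance
    inflation).  Includes a beta-binomial trial simulator with heterogeneous
    cluster sizes and a Monte Carlo driver that estimates type I error and
    power over scenario grids and classifies each method against the
    nominal band.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
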