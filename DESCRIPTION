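Package: qrsaem
Title: Quantile Regression for Linear Mixed Models via Stochastic
    Approximation EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits quantile regression linear mixed-effects models (QR-LMM)
    for longitudinal data by exact maximum likelihood under an asymmetric
    Laplace error law. Estimation uses the stochastic approximation EM
    (SAEM) algorithm with Metropolis-Hastings simulation of the subject
    random effects, a linear-programming (interior point) M-step for the
    fixed effects, closed-form scale updates, importance-sampled marginal
    log-likelihood, Louis-type and bootstrap standard errors, information
    criteria (AIC, BIC, HQC) for random-structure selection, and fitting
    over a grid of quantile levels. Includes a calibrated synthetic
    generator of CD4-count-like longitudinal cohorts for validation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
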