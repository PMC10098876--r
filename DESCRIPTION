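Package: seamtte
Title: Selection-Adjusted Estimation in Seamless Phase II/III Survival Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point estimation of log hazard ratios in two-stage seamless
    phase II/III (drop-the-loser) clinical trials with time-to-event
    endpoints, where experimental arms are selected at an interim analysis
    on the same data later used for the confirmatory estimate. Implements
    an approximate uniformly minimum variance conditional unbiased
    estimator (UMVCUE) together with naive, single- and multiple-iteration
    bias-subtracted and empirical-Bayes shrinkage estimators, for a family
    of threshold and pick-the-winner selection rules. Includes the
    stage-wise machinery (logrank score statistics, shared-control
    covariance of stage-1 log hazard ratios, independent-increment
    decomposition, Cox-model routes), truncated multivariate-normal
    rectangle probabilities and first moments, a Weibull multi-arm
    two-stage trial simulator for operating characteristics, and a
    Schoenfeld required-events calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mvtnorm,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
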