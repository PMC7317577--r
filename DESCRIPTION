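Package: sncstm
Title: Structural Nested Cumulative Survival Time Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Causal inference for the effect of a time-varying exposure on a
    survival outcome under time-varying confounding, using structural nested
    cumulative survival time models (SNCSTMs). The model parameterises, per
    follow-up visit, the additive effect on the conditional hazard of setting
    that visit's exposure to zero when all later exposures have already been
    set to zero. Three estimators are provided: a pseudo-individual GLM
    estimator computable with standard weighted least squares, a closed-form
    G-estimator based on counting-process estimating equations, and an
    improved G-estimator that refits the exposure nuisance model at every
    risk-set departure time. The package includes constrained (common
    lag-effect) estimation, stabilised blip weights, inverse-probability-of-
    censoring weighting, a counterfactual exposure-free survivor curve,
    subject-level bootstrap confidence intervals, and a simulation engine
    with a known-truth data-generating process for validating the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
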