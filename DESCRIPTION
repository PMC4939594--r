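Package: crtimbalance
Title: Consequences of Cluster-Level Covariate Imbalance in Cluster
    Randomized Trials
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and Monte-Carlo evaluation of two-arm cluster
    randomized trials with a binary cluster-level covariate. Plans the
    number of clusters from the standard design-effect sample-size
    formula, expresses chance covariate imbalance as quantiles of the
    hypergeometric distribution of the number of covariate-positive
    clusters randomized to the intervention arm, generates trials from a
    two-level random-intercept model, fits the covariate-adjusted and
    unadjusted linear mixed models by closed-form REML for balanced
    designs, and summarizes parameter bias, standard-error bias and
    empirical versus nominal power over a factorial grid of simulation
    conditions.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
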