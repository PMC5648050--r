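Package: elicitpmm
Title: Expert-Elicitation-Informed Pattern-Mixture Sensitivity Analysis for
    Trials with Missing Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensitivity analysis of randomised controlled trials
    whose quality-of-life outcomes may be missing not at random (MNAR).
    Expert beliefs about the outcomes of non-responders, captured as normal
    distributions on a bounded quality-of-life scale, are converted into
    bivariate normal priors on the arm-specific pattern-mixture sensitivity
    parameters, combined across experts by equal-weight linear pooling into
    a mixture prior, and propagated through both a closed-form moment
    estimator and a fully Bayesian pattern-mixture model of the treatment
    difference.  Includes a community-of-priors workflow (pooled groups plus
    most-sceptical and most-enthusiastic individual experts), tipping-point
    scans over fixed sensitivity-parameter values, density-strip summaries
    of posterior distributions, and seed-deterministic generators for
    synthetic trials with outcome-dependent missingness and synthetic
    expert panels with known belief structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
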