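Package: aksa
Title: Assessing the Predictiveness of a Continuous Biomarker in Small
    Two-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for the predictive value of a continuous baseline
    biomarker in small two-arm trials with a binary response endpoint.
    Implements the AKSA test (the Monte-Carlo probability that the
    logit-scale difference between the arm response curves increases
    between randomly sampled biomarker values) together with six
    established comparators: the treatment-by-biomarker Wald interaction
    test, its dichotomised minimum-p variant, the likelihood-ratio test,
    the STEPP sliding-window permutation test, a Bayesian
    cutoff-probability rule, and the DeLong comparison of per-arm ROC
    areas.  Includes a scenario engine that solves logistic
    outcome-model coefficients from target response rates and
    predictive/prognostic effects, a trial simulator, simulation-based
    calibration of each method's decision threshold to a common type-I
    error level, and an operating-characteristics study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
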