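Package: lagdml
Title: Lagged Discovery and Double Machine Learning for Longitudinal
    Initiation Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage causal interface for time-varying predictors of rare,
    absorbing binary initiation outcomes in longitudinal panel data. Stage
    one screens lagged predictors with class-weighted elastic-net logistic
    regression and subject-level bootstrap stability selection; stage two
    estimates adjusted effects for stable predictor-outcome edges by double
    machine learning partialling-out with subject-grouped cross-fitting and
    cluster-robust sandwich inference. Includes a synthetic panel generator
    with known lagged causal structure and a Monte-Carlo ground-truth
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
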