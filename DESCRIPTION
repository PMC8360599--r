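Package: postrun
Title: Derivation of a Clinical Decision Tool for Postpartum Running-Related Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the full derivation pipeline for a cumulative
    risk-factor clinical decision tool for running-related pain in
    postpartum runners: synthetic survey-cohort simulation with a
    calibrated logistic outcome model, eligibility screening and flow
    accounting, Little's test for completely-at-random missingness,
    pooled regression-based multiple imputation, ROC-midpoint
    dichotomization of continuous predictors, bivariate logistic
    screening with a p < 0.15 retention rule, Phi / Cramer's V
    multicollinearity filtering, backward-elimination multivariable
    logistic regression, and diagnostic-accuracy evaluation of the
    resulting "k or more of K risk factors" rule (sensitivity,
    specificity, likelihood ratios, and Bayes post-test probabilities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
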