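Package: rab5atools
Title: Qualifying-Biomarker Analysis of RAB5A as a Predictor of T-DM1 Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of the computational chain that qualifies
    RAB5A expression as a predictive biomarker for trastuzumab emtansine
    (T-DM1): sigmoid dose-response fitting with IC50 extraction and
    expression-sensitivity regression in a cell-line panel; per-arm logistic
    association and treatment-interaction likelihood-ratio testing of trial
    biomarkers; Monte-Carlo 2-fold cross-validated dichotomization-threshold
    discovery with logit-method p-value combination; Bayesian covariate-adjusted
    logistic estimation of pathologic-complete-response probabilities in
    biomarker subgroups; ROC/Youden optimal-cutoff analysis; and Allred-score
    based progression-free-survival comparison. Includes fully seeded synthetic
    generators for trial cohorts, viability panels and IHC cohorts with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    lmtest,
    optparse
Config/testthat/edition: 3
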