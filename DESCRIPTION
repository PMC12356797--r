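Package: triagedx
Title: Validation of AI-Plus-Human Sequential Triage for Diagnostic Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating sequential human-AI assessment
    procedures in diagnostic compensation settings, built around the asbestosis
    use case: three-way triage of an AI probability score (auto-negative,
    auto-positive, deferral to two independent reviewers), a three-expert
    majority reference standard with blinded reviewer allocation, diagnostic
    accuracy metrics (sensitivity, specificity, predictive values, ROC-AUC,
    PR-AUC) with percentile-bootstrap confidence intervals, paired correlated
    ROC-AUC comparison (DeLong), multi-rater agreement statistics
    (free-marginal Randolph kappa, Fleiss kappa, subgroup kappas, Kendall
    tau-b), exact binomial power design for one-sided sensitivity validation
    with Clopper-Pearson bounds, and a synthetic cohort generator with
    correlated binary raters for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
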