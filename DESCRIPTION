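Package: fairaudit
Title: Gender-Bias Auditing and Mitigation for Small-Cohort Behavioral Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits binary classifiers of phone-sensed mental-health status for
    group (gender) bias and mitigates it by preprocessing alone. Provides a
    synthetic cohort generator emulating small mobile-sensing studies (subgroup
    feature shift, negative-legacy label deficits), a leakage-free preprocessing
    chain (median imputation, standardization, SMOTE on training folds only,
    PCA), five classifier families behind one fit/predict contract, the common
    group-fairness metrics (delta accuracy, delta TPR, delta FPR, statistical
    parity difference, disparate impact) plus the balanced error rate, a
    from-scratch disparate impact remover with partial (lambda) repair via
    within-group quantile alignment, and a repeated stratified cross-validation
    harness that aggregates metrics over shuffled iterations with two-tailed
    t tests, before and after repair.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    ranger,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
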