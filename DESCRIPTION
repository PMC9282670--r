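Package: sccat
Title: Computerized Adaptive Testing and Classification of Skin Cancer Risk
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rasch partial credit model tools for skin-cancer risk
    assessment: a calibrated 30-item difficulty bank, simulation of
    virtual respondent cohorts, a computerized adaptive testing (CAT)
    engine with Newton-Raphson ability estimation, maximum-information
    item selection, SEM-based stopping and infit/outfit person-fit
    diagnostics, three reference classifiers (Gaussian naive Bayes,
    k-nearest neighbors, logistic regression), and an evaluation
    calculus producing single-operating-point and full ROC AUCs with
    normal-approximation confidence intervals under hold-out and k-fold
    validation. Also computes per-item standardized mean differences
    with Cochran's Q heterogeneity for forest-plot summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
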