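Package: mirfuse
Title: Integrative MicroRNA Target Scoring from Prediction Algorithms and
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combines target-site scores from sequence-based microRNA
    target prediction algorithms (miRanda alignment scores, PicTar scores,
    TargetScan conserved-targeting probabilities) with miRNA-mRNA
    expression-association p-values through a logistic (sigmoidal)
    integration model trained against an experimentally supported gold
    standard.  Provides the per-pair expression association step (simple
    linear regression with a negative-slope rule), feature assembly with
    configurable gold-standard variants and missing-data policies, ROC/AUC
    evaluation with Hanley-McNeil standard errors and correlated-AUC
    comparison, K-fold cross-validation of the fitted model, and a
    synthetic-data generator with planted regulatory structure so the whole
    pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    boot,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
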