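Package: pabrain
Title: Linking Accelerometer-Derived Physical Activity to Brain
    Image-Derived Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-stage analysis pipeline relating accelerometer-derived
    physical-activity summaries to brain image-derived phenotypes
    (functional-connectivity edges and regional gray-matter volumes).
    Stage one is bipartial canonical correlation analysis (each block
    residualized on its own confounders) with Bartlett approximation and
    permutation inference, per-mode variance explained and cross-loadings.
    Stage two is mass-univariate screening with Benjamini-Hochberg control,
    repeated cross-validated predictive correlation, and three
    variable-importance engines (per-coefficient t-tests, stepwise BIC,
    random-forest permutation importance).  Stage three fits nested
    logistic disease-risk models compared by vertically averaged ROC
    curves, cross-validated AUC and test-set McFadden pseudo-R-squared.
    Includes derivation of eleven physical-activity features from
    minute-level acceleration traces and a synthetic-cohort generator
    with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
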