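Package: pneumotext
Title: Pneumothorax Detection in Radiology Reports After Central Venous
    Catheter Procedures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible text-mining and biostatistics pipeline for
    estimating pneumothorax incidence after central venous catheter (CVC)
    insertion and removal from free-text radiology reports. Includes a
    seeded synthetic corpus generator (demographics, outcome model, German
    and English report lexicons with abbreviations, misspellings, negated
    mentions and contraindication phrases), rule-based phrase matching with
    negation precedence, bi-gram document-term matrices with document
    frequency pruning, SMOTE minority oversampling implemented from the
    interpolation formula, a Gini-split random forest classifier, held-out
    evaluation with ROC/AUC, an ablation grid, and the accompanying
    epidemiological analyses (2x2 chi-square, logistic regression by
    iteratively reweighted least squares, linear model of pneumothorax
    size, incidence summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    ranger,
    tibble,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    pROC,
    optparse
Config/testthat/edition: 3
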