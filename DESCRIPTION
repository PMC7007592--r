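Package: phenotext
Title: Computable Phenotyping from Clinical Notes with Regular-Expression Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns corpora of free-text clinical notes into patient-level
    feature vectors using clinician-authored regular-expression features and a
    fixed sentence-to-note-to-patient aggregation, then trains and
    cross-validates standard classifiers (linear support vector machine,
    Gaussian naive Bayes, decision tree, random forest) to assign each patient
    a phenotype class with a confidence score. Includes blinded held-out
    evaluation, confusion-matrix diagnostics (sensitivity, specificity, PPV,
    NPV, F1, AUROC), confidence-cutoff abstention analysis, a synthetic
    clinical-note corpus generator with planted phrases for end-to-end
    testing, and a command-line pipeline with reproducible run manifests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    pROC,
    stringr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
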