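Package: omcscreen
Title: Drug-Response Classifier Screening with Merged Cross-Validation and
    OMC Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Large-scale screening of tumor molecular profiles for drug-response
    prediction in small oncology cohorts. Implements clinical cohort curation
    (drug-name standardization, response binarization, exclusion rules),
    per-profile preprocessing for expression, methylation and copy-number data,
    a merged stratified K-fold cross-validation engine that pools all
    out-of-sample predictions before computing the Matthews correlation
    coefficient and ROC-AUC once per repetition, optimal-model-complexity (OMC)
    nested cross-validation feature selection over an ANOVA-ranked top-k grid,
    an eight-algorithm classifier registry, single-gene and class-permutation
    baselines, and Kaplan-Meier, log-rank and Cox comparison of actual versus
    predicted responder groups. A seeded synthetic-data generator with planted
    informative features and survival effects makes the whole pipeline testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
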