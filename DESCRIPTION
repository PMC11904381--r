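Package: cbcscreen
Title: Cautious Sepsis Screening Models from Complete Blood Count and
    Monocyte Distribution Width
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and external-validation tooling for machine-learning
    sepsis screening models built on complete blood count (CBC) parameters and
    the monocyte distribution width (MDW). Provides a parametric synthetic
    cohort generator with controllable covariate, label and missingness
    shifts; tuned three-step classification pipelines (scaling, recursive
    feature elimination, classifier) with stratified cross-validated random
    search; cautious (abstaining) classification with high-confidence metrics
    and coverage, including a printed two-feature partial decision rule;
    evaluation metrics (sensitivity, specificity, PPV, NPV, AUC, average PPV,
    Brier score, standardized net benefit) with Wald, rank-statistic and
    Hoeffding confidence intervals; chi-square model comparisons with the
    Gavrilov-Benjamini-Sarkar adaptive step-down false discovery rate
    procedure; and a random-forest imputation stage for cohorts lacking MDW.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    rpart,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
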