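Package: picuews
Title: Multi-Horizon Deterioration Prediction and Alert-Burden Simulation
    for Pediatric Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and evaluating early-warning systems for
    critical deterioration events (cardiopulmonary resuscitation, ECMO
    initiation, dilute-epinephrine bolus, unplanned intubation) in the
    pediatric intensive care unit.  Constructs analysis cohorts from raw
    admission, event and observation tables (admission merging, 48-hour
    unplanned-intubation confirmation, 8-hour event deduplication, temporal
    splits, horizon-labelled training samples); extracts windowed summary
    features from irregular medication, laboratory and vital-sign streams;
    trains an ensemble of per-horizon classifiers (gradient-boosted trees,
    random forest or L1-regularised logistic regression) whose averaged
    probability forms a single risk index; evaluates discrimination with
    AUROC/AUPRC, stratified bootstrap confidence intervals, paired DeLong
    tests, Benjamini-Hochberg correction and subgroup fairness slices; and
    -- centrally -- emulates prospective deployment of any risk score or
    binary alerting tool to quantify the tradeoff between event detection
    and alert burden under configurable prediction intervals, thresholds,
    refractory periods and post-event censoring.  A synthetic electronic
    health record timeline generator with a controllable pre-event
    physiologic deterioration signature makes the whole pipeline testable
    without access to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    ranger,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
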