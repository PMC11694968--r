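Package: injurycast
Title: Daily Noncontact-Injury Risk Prediction for Professional Footballers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A season-scale pipeline for predicting daily noncontact injuries of
    professional football players from GPS-derived external-load metrics and
    descriptive variables. Provides a seeded synthetic season generator with a
    load-spike injury hazard; exercise-to-day aggregation with dummy-day
    insertion and one-hot encoding; adaptive winsorization with bounds fitted on
    injured players' records followed by z-score standardization; greedy
    minimum-redundancy maximum-relevance (mRMR) feature ranking with a top-p
    wrapper sweep; cost-sensitive support vector machines, feedforward neural
    networks and AdaBoost stump ensembles with k-means centroid undersampling;
    player-disjoint two-fold validation with ROC-elbow threshold selection; and
    GMEAN-based model selection with stability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
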