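Package: alstrack
Title: Semi-Supervised Tracking of ALS Functional Decline from In-Home Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating between-visit trajectories of the Revised ALS
    Functional Rating Scale (ALSFRS-R) from continuous in-home sensor
    monitoring. Sparse monthly assessments are expanded to daily pseudo-labels
    by piecewise-linear, natural cubic spline, and ensembled shallow
    self-attention interpolation; daily day/night sensor summary features are
    built, decorrelated and min-max normalized; gradient-boosted regression
    models are trained under three paradigms (individual batch, cohort
    transfer with batch fine-tuning, cohort transfer with prequential
    incremental fine-tuning) using leave-one-participant-out folds, randomized
    hyperparameter search and a precision-rounding feature screener; and
    models are evaluated with RMSE bootstrap intervals, Fisher-z correlation
    intervals and Taylor-diagram coordinates. A seeded synthetic-cohort
    generator provides sensor streams, sparse assessments and ground-truth
    latent trajectories so the whole pipeline is testable without access to
    restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
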