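Package: survkit
Title: Probabilistic Machine-Learning Framework for Right-Censored
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A unified task/learner/prediction/measure architecture for
    single-event right-censored survival analysis. Provides validated
    survival tasks, discrete-time survival-distribution prediction
    objects, reference learners (Kaplan-Meier, Nelson-Aalen, Cox
    proportional hazards with Breslow ties, Weibull accelerated failure
    time) implemented from first principles, censoring-adjusted
    evaluation measures (Harrell and Uno concordance, time-dependent
    AUC, integrated Graf/Brier score, integrated log-loss, Schmid
    absolute score, van Houwelingen's calibration slope, Kaplan-Meier
    calibration), prediction-type composition pipelines (proportional
    hazards, accelerated failure time, proportional odds forms),
    cross-validated benchmarking with paired folds, and a synthetic
    right-censored survival-data simulator with censoring-rate
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
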