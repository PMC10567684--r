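Package: scanopt
Title: Choosing and Validating Scan-Sampling Intervals for Group
    Behavioral Observation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A multistep toolkit for deciding how often to scan a group of
    animals when continuous behavioral recording is infeasible.  Converts
    continuous behavior timelines into scan tables at arbitrary sampling
    intervals, selects a reference interval against continuous recording
    (R-squared, MAE, RMSE), quantifies reliability with two-way intraclass
    correlation coefficients, accuracy with signed error scores and
    Bland-Altman limits of agreement (raw and percent modes), and validity
    by comparing Tweedie-GLM effect sizes across sampling methods.  A
    semi-Markov flock simulator supplies ground-truth timelines with
    controllable time budgets, bout lengths, visibility and group effects,
    so every stage of the workflow can be exercised and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    mgcv,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
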