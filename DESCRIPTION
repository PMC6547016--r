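Package: newsfio2
Title: FiO2-Augmented National Early Warning Scores for Ward Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fractional inspired oxygen concentration (FiO2)
    from routinely recorded oxygen-delivery observations using a dilution
    formula, derives FiO2 scoring bands from event-labelled ward data with a
    single-feature classification tree, scores vital-sign observation sets
    with the National Early Warning Score (NEWS) and its FiO2-augmented
    variant (NEWS-FiO2), and evaluates both scores against a 24-hour
    death or unplanned intensive-care-admission outcome using AUROC with
    stratified bootstrap confidence intervals, precision-recall and
    efficiency curves, and operating-point statistics. Includes a synthetic
    ward-data generator so the full pipeline is exercisable without access
    to hospital databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
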