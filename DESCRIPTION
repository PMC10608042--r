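Package: behaviorcast
Title: Individualized Next-Day Challenging-Behavior Prediction from Daily
    Clinical and Environmental Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cleans multi-source daily records kept for residents of a care
    facility (behavior logs per 8-hour shift, nightly sleep checks, bowel
    movement events with Bristol scores, menses, pollen counts, weather
    station values, and lunar ephemerides), engineers prior-day predictors,
    applies cohort inclusion criteria, and fits one direct-kernel ADALINE
    classifier per individual to predict whether a challenging behavior
    (aggression and/or self-injury) occurs the next day.  Models are
    evaluated by the balanced classification rate over repeated random
    85:15 splits, variable importance is measured by single-variable
    excitation of the fitted network, and predictor redundancy is summarized
    by correlation-based hierarchical clustering.  A synthetic-cohort
    generator with known ground truth makes every stage testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
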