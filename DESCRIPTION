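Package: bpmenu
Title: Personalized Antihypertensive Prescription from Longitudinal Blood-Pressure Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds visit-level cohorts from event-stream electronic health
    records, fits per-drug-class outcome regressions (including a
    distributionally robust absolute-loss regression immunized against outcome
    outliers), predicts counterfactual next-period systolic blood pressure for
    each option on a menu of antihypertensive drug classes with a
    coefficient-weighted nearest-neighbor estimator, and turns those
    predictions into rule-constrained randomized prescription recommendations.
    Ships a longitudinal synthetic-cohort generator with ground-truth
    counterfactual outcomes and an evaluation harness for comparing model
    policies against standard of care.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
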