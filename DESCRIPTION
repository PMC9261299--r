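Package: actage
Title: Biological Age from Wearable Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts biological age from week-long minute-level wearable
    accelerometer counts in NHANES-style cohorts. Reduces each participant's
    7 x 1440 intensity grid to 336 hourly max/variance features, trains a
    random-forest age regressor, applies a peer-median normalization to obtain
    a deltaAge aging-acceleration statistic, relates aging classes to
    mortality, and screens nutrient intakes and prescription drugs for
    association with decelerated aging. Includes a fully synthetic cohort
    generator with planted effects so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    dplyr,
    generics,
    ggplot2,
    haven,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
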