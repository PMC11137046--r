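Package: sauronCP
Title: Reliable Drug-Sensitivity Prediction and Prioritization with
    Conformal Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous regression and classification random forests
    (SAURON-RF) with class-imbalance sample weighting and a quantile
    regression extension, wrapped in a split conformal-prediction layer
    that turns model uncertainty into prediction sets and intervals with
    user-specified certainty guarantees. Includes the CMax-viability
    drug-sensitivity measure computed from raw dose-response data with
    across-drug PAM-based discretization, a cell-line-centric drug
    prioritization pipeline, evaluation metrics, seeded synthetic-data
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    randomForest,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
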