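Package: insulinrl
Title: Offline Distributional Reinforcement Learning for Hourly Insulin
    Dosing in the ICU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for learning and evaluating hourly regular-insulin dosing
    policies for the first day after cardiac surgery from logged ICU
    trajectories. Implements a piecewise glycemic reward with a quadratic
    dose penalty, a synthetic post-cardiac-surgery glucose-insulin cohort
    simulator with a sliding-scale behaviour policy, a preprocessing
    pipeline that turns patient-hour tables into normalized transition
    datasets (exclusion filters, hourly binning, forward-fill plus k-nearest
    neighbour imputation, min-max normalization), a conservative Q-learning
    agent with an implicit-quantile distributional critic and
    return-weighted batch sampling, fitted-Q off-policy evaluation with
    percentile-bootstrap confidence intervals and max-lower-bound model
    selection, and descriptive policy analyses (time in range, cumulative
    dose differences, dose-by-glucose profiles, agreement and disagreement
    summaries, permutation feature importance).
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
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    arrow
Config/testthat/edition: 3
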