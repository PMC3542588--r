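Package: edgam
Title: Space-Time Mapping of Emergency Department Case-Control Data with
    Loess Generalized Additive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level space-time analysis of emergency-department-style
    case-control point data. Fits logistic generalized additive models with
    tri-cube locally weighted (loess) smooth terms for location or time by
    local scoring, selects the smoothing span by AIC, divides a study period
    into overlapping time windows chained on median days, predicts adjusted
    odds-ratio surfaces on a clipped rectangular grid, screens each window
    with a global deviance permutation test, flags pointwise hot and cold
    spots from the same permutations, and renders the window series as a
    shared-scale map animation. Includes a seeded synthetic data generator
    with known spatial-temporal risk structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    png,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
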