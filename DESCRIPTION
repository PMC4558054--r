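Package: choflux
Title: Dynamic Kinetic Modelling and Metabolic Flux Analysis of CHO Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-parameter-set dynamic metabolic model of monoclonal-antibody
    producing CHO cells covering glycolysis, the TCA cycle, the pentose phosphate
    pathway, amino acid metabolism and energetics. Provides a batch and fed-batch
    bioreactor simulator with discrete bolus feed events, Morris elementary-effects
    screening for global parameter sensitivity, weighted nonlinear least-squares
    calibration with linearized confidence intervals, dynamic metabolic flux
    analysis with delta-method flux confidence bands, and a synthetic-data
    generator that emulates batch and fed-batch cultures on two media so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
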