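Package: dielmetab
Title: Stream Metabolism from Diel Dissolved-Oxygen Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating daily stream metabolism (gross primary
    production, ecosystem respiration and gas exchange) from high-frequency
    dissolved-oxygen sensor records using a one-station state-space model
    with process and observation error, fitted by Markov chain Monte Carlo
    over an exact Kalman-marginalised likelihood. Includes automated sensor
    QAQC (storm-clog removal, despiking, smoothing, diel-signal and drift
    screening), modeled clear-sky light and temperature/leaf-out season
    classification, potential-incident-light metrics, upstream-downstream
    wastewater-treatment-plant amplification statistics, moving-window
    dissolved-oxygen criteria analysis for regulatory monitoring design,
    and a synthetic diel-oxygen generator with known parameters and
    realistic sensor artifacts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
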