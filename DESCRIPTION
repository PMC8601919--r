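Package: tnztools
Title: Thermoneutral Zone Estimation and Evaporative Cooling Analysis
    from Flow-Through Respirometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for avian thermal physiology: reduction of open
    flow-through respirometry traces to steady-state oxygen consumption
    and evaporative water loss (baseline drift correction, lowest stable
    window extraction, gas exchange equations), continuous piecewise
    linear (breakpoint) regression for estimating the limits of the
    thermoneutral zone and the inflection point of evaporative water
    loss, appendage surface-area morphometrics with sex-stratified
    relative-size indices, evaporative cooling efficiency (EHL/MHP),
    and small-sample information-theoretic model selection (AICc,
    Akaike weights, model averaging, relative importance weights).
    Includes a synthetic-data generator that emulates the statistical
    structure of a stepped-temperature metabolic trial on a small
    passerine, so the whole pipeline can be exercised and validated
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
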