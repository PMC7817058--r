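Package: ribocomb
Title: Growth-Law Based Prediction of Interactions Between
    Ribosome-Targeting Antibiotics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts full two-drug (and approximate three-drug)
    dose-response surfaces of ribosome-targeting antibiotics from
    single-drug response parameters, using a minimal biophysical model
    built on bacterial growth laws.  Covers the single translation
    inhibitor model (cubic steady state, bistability and the exact
    bifurcation point), the two-drug mass-action system with direct
    binding interaction modifiers, Loewe additive and Bliss reference
    surfaces with interaction scoring, slow-growth analytic limits,
    three-drug occupancy-diagram solutions and their consistency with
    mechanism-independent maximum-entropy predictions, and extensions
    for starvation-mimicking antibiotics and constitutively expressed
    resistance genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
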