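Package: trogoscale
Title: Mechanical Scaling Analysis of Macrophage Trogocytosis and Phagocytosis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for the decision between
    macrophage trogocytosis (membrane 'nibbling') and phagocytosis (complete
    engulfment) of antibody-opsonized targets. Estimates cortical or membrane
    tension from micropipette aspiration via the Young-Laplace law, classifies
    three-channel flow-cytometry events into trogocytic and phagocytic classes
    and computes efficiencies, converts fluorescence intensity to antibody
    surface density with MESF calibration beads, fits logistic dose-response
    curves to extract the critical antibody density at the inflection point
    with bootstrap confidence intervals, and implements an interfacial
    force-balance scaling model predicting bite size and the phase boundary
    between trogocytosis and phagocytosis. Includes synthetic-data generators
    with known ground truth for every input, so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
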