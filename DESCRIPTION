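Package: ionclamp
Title: Voltage-Clamp Simulation and Model-Free Kinetic Scoring of Ion
    Channel Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative, model-free characterization of voltage- and
    calcium-gated ion channel kinetics. Hodgkin-Huxley style channel models
    are simulated under five standardized voltage-clamp protocols
    (activation, inactivation, deactivation, ramp, action potential), the
    resulting current traces are normalized, subsampled and reduced to
    low-dimensional kinetic score vectors by a two-stage principal component
    analysis, and channels are grouped by Ward hierarchical clustering of
    score distances. New simulated or experimentally recorded traces can be
    projected into a fitted score space and compared against a reference
    ensemble. Includes a synthetic ensemble generator with known ground
    truth, genealogy (ancestor-descendant) utilities, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    igraph,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
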