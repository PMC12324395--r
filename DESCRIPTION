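Package: gridshift
Title: Run-by-Run Grid-Field Tracking, Toroidal Phase Analysis, and
    Attractor-Network Modeling of Grid-Cell Map Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how entorhinal grid cells remap during
    spatial learning on virtual linear tracks. Implements a four-stage
    run-by-run field detection and cross-day linking pipeline for spatially
    binned calcium activity, rotation-bootstrap classification of backward,
    forward and stationary field shifts, day-field stabilization and
    overnight reset statistics, landmark interaction analyses, toroidal
    population-phase extraction from Welch periodograms, an
    entorhinal-hippocampal continuous-attractor circuit model with delayed
    online-pseudoinverse plasticity and slow consolidation, and a
    key-value-memory position decoder. A synthetic-data generator with
    known ground truth (drifting fields, landmark arrest, co-modular
    populations on a shared triangular lattice) makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
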