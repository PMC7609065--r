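Package: fretsort
Title: Simulation, Deep Sequence Classification and Kinetic Analysis of
    Single-Molecule FRET Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for automated quality sorting of single-molecule FRET
    (smFRET) fluorescence time traces. Provides a generative simulator for
    ground-truth ALEX and non-ALEX traces covering photobleaching, blinking,
    aggregates, detection artifacts and scrambled (non-FRET) behaviour; a
    per-frame six-class sequence classifier built from residual convolutions
    and a bidirectional LSTM, trained entirely on simulated data; a
    confidence-score acceptance rule with sliding-window photobleaching
    detection; baseline stoichiometry/intensity threshold sorting with
    precision-recall benchmarking; and downstream hidden Markov model
    idealization with BIC state-number selection, dwell-time and
    transition-density statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
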