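Package: dynastim
Title: State-Dependent Effects of Single-Pulse Stimulation in Whole-Brain
    Oscillatory Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation of a connectome-coupled network of
    exact mean-field excitatory/inhibitory neural masses, with tools to
    characterize its collective oscillatory regimes (rate statistics and
    phase-locking values), extract discrete dynamic functional-connectivity
    (FC) states from sliding-window phase-locking and phase-lag patterns,
    measure FC-state-conditioned effective phase-response curves and
    stimulation-induced state-switching probabilities for phased
    single-pulse perturbations, and quantify how FC-state-aware features
    improve random-forest prediction of stimulation-induced phase shifts.
    Includes surrogate connectome and planted-synchrony generators so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    pracma,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
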