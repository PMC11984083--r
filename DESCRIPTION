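Package: synchrostim
Title: Kuramoto-Network Simulation and Response-Curve Analysis of
    Phase-Locked Stimulation
Version: 0.1.0
Authors@R:
    person("Synchrostim", "Developers", email = "synchrostim@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how oscillatory neuronal populations respond
    to phase-locked electrical stimulation. Provides a finite-size stochastic
    Kuramoto simulator with a closed-loop phase-triggered pulse controller,
    the mean-field (reduced) two-equation model for synchrony and mean phase,
    an ECoG-style signal-conditioning chain (artifact interpolation,
    anti-aliased downsampling, zero-phase Butterworth band-pass, Hilbert
    envelope and phase), block- and pulse-based amplitude and phase response
    curve estimators with their associated statistics, a feature-matching
    model-fitting routine based on spectral and envelope statistics with a
    parameter-recovery harness, a synthetic-data generator with stored ground
    truth, and a minimal Hodgkin-Huxley demonstration of the biphasic (type
    II) single-neuron phase response.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
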