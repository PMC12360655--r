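Package: lamwave
Title: Laminar Neural-Mass Modelling of Forward and Backward Alpha Traveling Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hierarchical laminar mean-field model of visual
    cortical areas in which infragranular populations of intrinsically
    bursting spiking neurons act as alpha-band (~10 Hz) pacemakers. The
    network generates spontaneous backward (anterior-to-posterior)
    traveling waves at rest and reverses to forward waves under sensory
    stimulation. Includes an optional trans-pulvinar feedforward pathway
    that biases the network toward spontaneous forward waves, a simulated
    64-channel EEG forward projection with an analytic spherical dipole
    lead field and 1/f noise sources, and a phase-gradient plane-fitting
    procedure with circular-correlation statistics that classifies
    scalp-level wave direction against an electrode-permutation null.
    Experiment drivers reproduce response curves, impulse responses,
    state time-courses, spectral analyses, delay sweeps, pulvinar sweeps
    and lateralized (two-hemisphere) simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
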