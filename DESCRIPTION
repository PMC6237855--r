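Package: hbdyn
Title: Hydrogen-Bond Rearrangement Dynamics and Vibrational Echo Observables in Liquid Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for hydrogen-bond network dynamics in
    liquid water from molecular-dynamics trajectories and per-pair
    energy-decomposition output.  Computes instantaneous OH stretch
    frequencies by a continuous wavelet transform with a Morlet-Grossman
    mother wavelet, hydrogen-bond strength and charge-transfer metrics and
    a local solvent reorganization index, their time-correlation functions
    with bi-exponential fits and block-averaged uncertainties, linear
    frequency-energy maps, and third-order photon-echo observables (the
    short-time slope of the integrated three-pulse echo, S3PE) in the
    second-order cumulant approximation.  Includes seeded synthetic
    generators (Ornstein-Uhlenbeck frequency processes, two-state Markov
    hydrogen bonds, analytic oscillator trajectories) so the entire
    pipeline is testable without running molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
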