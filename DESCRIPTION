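Package: perivasc
Title: Perivascular Space Dynamics, CSF Flow and Solute Transport Across
    the Sleep Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses sleep-cycle-dependent vessel diameter
    dynamics and their predicted consequences for cerebrospinal fluid flow
    and solute transport in perivascular spaces. Provides a synthetic-data
    generator (hypnograms, lumen/endfoot diameter traces, two-photon x-t
    linescan stacks, ECoG/EMG), automated linescan diameter extraction,
    frequency-band decomposition with oscillation-event statistics and
    rule-based sleep-state scoring, a quasi-steady Stokes model of
    oscillatory flow in a deforming annular perivascular space, and a
    conservative finite-volume advection-diffusion solver for oscillatory
    dispersion enhancement and solute influx front tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
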