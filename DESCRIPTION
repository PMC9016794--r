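Package: multisync
Title: Multi-Synchronization of Bidirectionally Coupled Biological Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulation and census of coexisting synchronization modes
    (multi-rhythmicity) of two bidirectionally coupled limit-cycle
    oscillators, built around a circadian-clock-like negative-feedback
    oscillator and a cell-cycle-like relaxation oscillator coupled through
    clock-driven Wee1 induction and Cdk1-dependent mitotic repression of
    clock transcription. Provides deterministic ODE integration with exact
    coupling-onset events and pulse perturbations, limit-cycle period
    estimation and attractor fingerprinting, coupling-onset-time sweeps that
    sample basins of attraction, two-parameter synchronization diagrams and
    period surfaces, hysteresis sweeps, Arnold-tongue entrainment maps, and
    pulse-induced switching maps. An analytic multi-limit-cycle normal-form
    oscillator with exactly known attractors serves as a built-in oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
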