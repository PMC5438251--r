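Package: redoxadapt
Title: Feedback Models of Hydrogen Peroxide Homeostasis and Stress Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of intracellular hydrogen
    peroxide (H2O2) homeostasis through negative transcriptional feedback on
    antioxidant (peroxiredoxin-like) expression. Provides four nested feedback
    variants (integral, linear, saturating transcription, fully nonlinear
    scavenging), closed-form steady states and ramp asymptotics, numerical
    integration under arbitrary piecewise stress protocols (steps, linear
    ramps, mixing-tank ramps, pretreatment/challenge pulses), phase-diagram
    computation of the adaptation/arrest boundary in the (amplitude, ramp
    rate) plane, acquired-tolerance analysis, chi-square fitting of
    steady-state dose-response readouts, and generators of synthetic
    dose-response datasets and single-cell volume/budding traces with a
    budded-cell growth-rate estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
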