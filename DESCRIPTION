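Package: steadytorque
Title: Analysis and Simulation of Fixed-End Torque-Reduction Contractions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for fixed-end (isometric joint) dorsiflexion
    contraction trials: zero-phase Butterworth conditioning of dynamometer and
    surface EMG signals with multi-pass cut-off correction, active-torque and
    EMG linear-envelope computation, MVC-based normalization, designed
    trapezoidal torque-trace generation and trial-validity gating, hold-phase
    torque/EMG/fascicle metrics including torque steadiness (coefficient of
    variation) and ultrasound-derived fascicle lengthening amplitudes and
    rates, and a repeated-measures statistics layer (repeated-measures
    correlation, within-subject ANOVA with Mauchly/Greenhouse-Geisser
    sphericity handling, Holm-Sidak step-down comparisons, paired-design
    power). Includes a Hill-type muscle-tendon-unit simulator in which a
    drop in activation causes series-elastic recoil and fascicle lengthening,
    used to generate fully synthetic test datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
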