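Package: mesochoice
Title: Distributed Choice Signals in Mesoscale Cortical Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how perceptual
    choice, stimulus, movement and sustained-attention signals are
    distributed across mouse posterior cortex in widefield calcium imaging.
    Provides a synthetic-session generator with planted low-dimensional
    signals, dF/F preprocessing with dual-wavelength hemodynamic correction,
    a seeded localization-penalized non-negative matrix factorization that
    assigns spatial-temporal components to cortical areas, cross-validated
    state-axis discriminability (d') analysis for task variables,
    representational-geometry statistics (axis angles, surrogate nulls,
    spatial-distribution index, piecewise d' fits, pixel-wise decoding
    controls), and a small recurrent network model of the decision process
    trained on psychometrically generated choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
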