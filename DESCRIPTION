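Package: saccadapt
Title: Saccade Adaptation Analysis with Synthetic Oculomotor Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for double-step saccade adaptation
    experiments: simulation of 1 kHz gaze recordings with main-sequence
    saccades and trial-to-trial oculomotor learning, velocity-threshold
    saccade detection, blink handling and trial-level rejection rules,
    exponential adaptation time-course fits, bivariate contour ellipse
    area (BCEA) fixation-stability statistics, lag-1 serial-dependence
    regression between post-saccadic error and visual localization,
    Autism-Spectrum Quotient scoring with median-split grouping, and
    default-prior JZS Bayes factors for t designs. A seeded synthetic
    cohort generator with known ground-truth learning parameters makes
    every analysis stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
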