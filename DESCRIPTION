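Package: scarindent
Title: Motor-Driven Ultrasound Indentation Analysis of Scar Tissue
    Thickness and Viscoelasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for motor-driven ultrasound
    indentation of soft-tissue layers such as hypertrophic scars. Provides a
    synthetic acquisition generator (M-mode echo frames plus a force channel
    under a cyclic loading protocol), echo interface tracking to recover
    tissue thickness and deformation, inversion of force-deformation curves
    to effective Young's moduli through the bonded-layer (Hayes-type) flat
    punch correction factor, segmentation of the J-shaped response into toe,
    heel and linear region moduli (E1/E2/E3), and cohort statistics
    (paired t-tests, one-way ANOVA with Fisher LSD post hoc, and Pearson
    correlation reports) for multi-arm negative-pressure-therapy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
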