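Package: ocuvib
Title: Finite-Element Vibrography Modelling of Corneal Elasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric finite-element harmonic-response simulation of
    corneal flaps and whole eye globes under acoustic excitation, as used in
    optical-coherence-tomography vibrography. Implements Prony-series
    viscoelastic solids, acoustic fluid elements with fluid-structure
    coupling for the ocular humours, stress stiffening from mounting stress
    or intraocular pressure, frequency-response and mode-shape analysis,
    one-at-a-time parameter sensitivity studies, and iterative inversion of
    resonance frequencies to corneal elasticity. A synthetic-data module
    generates vibrography displacement records and noisy frequency-response
    functions with known ground truth so the full pipeline can be exercised
    without measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
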