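Package: swimRFT
Title: Resistive-Force-Theory Modelling and Video-Based Quantification of
    Multi-Flagellated Bacterial Swimming
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physics of peritrichously flagellated bacterial swimming at low
    Reynolds number. Implements a resistive-force-theory (RFT) propulsion
    model of a cell driven by a rigid effective flagellar bundle: anisotropic
    filament friction coefficients (Gray-Hancock and Lighthill variants), the
    helix propulsion matrix, Perrin prolate-spheroid cell-body drag with a
    wobble projection, and the force/torque balance solved under a
    constant-motor-speed constraint. Population ensembles over cell geometry
    and motor orientation predict swimming speed versus flagellar number,
    with empirical expression-to-flagellation couplings and a
    single-parameter calibration against observed curves. The model is
    validated against video-based motility quantification: differential
    dynamic microscopy (image structure function plus a mixed
    swimmer/diffuser intermediate scattering function with Schulz-distributed
    swimmer speeds) and flicker rotation spectra (body and flagellar rotation
    peaks whose sum is the motor frequency). Seeded synthetic-data generators
    provide movies, intensity traces and flagellation tables with attached
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
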