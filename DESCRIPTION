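Package: magstimkit
Title: Calibration and Artifact Analysis for Magnetic Stimulation in
    Physiology Setups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for generating and verifying magnetic stimuli in
    space-constrained electrophysiology setups: Biot-Savart field models for
    square and circular Helmholtz-type coil pairs with homogeneity
    optimization, a forward model and ellipsoid calibration for miniature
    AMR vector magnetometers, affine calibration of a tri-axial coil system
    with control-voltage inversion, a behavioral model of a
    voltage-controlled coil current driver with double-wrapped sham
    blanking, and synthetic multielectrode-array recordings for separating
    magnetic induction artifacts from biological spikes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
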