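Package: vesiq
Title: Quantal and Spatial Analysis of Fluorescent Neurotransmitter Sensor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse fluorescence imaging of
    genetically encoded neurotransmitter sensors: release-site detection on
    pixel-wise maximal dF/F0 maps, classic equal-spacing quantal analysis
    (quantal size, release probability, vesicular quanta), spatial diffusion
    profiling (exponential spread length constant, half-maximum shape
    metrics, egress-outlet counting, radial band integrals), sigmoidal
    concentration calibration, and synaptic-versus-volume transmission
    classification with a distal electrochemical-style point detector.
    Includes a synthetic movie generator embodying the underlying
    release/diffusion/transporter-clearance/sensor model (categorical
    vesicular quanta, 2-D reaction-diffusion with zone-dependent first-order
    clearance, first-order sensor kinetics, camera shot noise) so every
    analysis stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
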