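Package: onhpleth
Title: Video Plethysmography of the Optic Nerve Head
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cardiac-cycle video plethysmography of the
    optic nerve head (ONH) from fundus video sequences: rigid frame-to-frame
    registration, ONH and vessel segmentation to form the microvascular tissue
    region of interest, trend-corrected pulsatile absorption signal extraction,
    pulse selection and averaging, waveform parameterization (peak amplitude,
    steepness, time-to-peak, full width at half maximum, duration), and the
    nonparametric group-statistics layer used to compare glaucoma stages.
    Includes a synthetic fundus-video phantom and cohort generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
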