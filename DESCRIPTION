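Package: plateletquant
Title: Quantitative Analysis of Platelet Activation from Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying platelet activation from
    super-resolution (STORM) images: simulation of synthetic platelet scenes
    with full ground truth, spot detection and integrated-Gaussian PSF
    fitting, fiducial- and cross-correlation-based drift correction,
    localization rendering, organelle cluster segmentation (median filter,
    Otsu threshold, 8-connected labeling, boundary dilation) with per-cluster
    statistics, annulus-normalized radial centralization profiles,
    orientation-histogram directionality analysis with a Gaussian peak-fit
    non-homogeneity statistic, nodule-offset morphometrics, time-course
    summaries, and similarity-transform registration for correlative
    STORM/EM overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
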