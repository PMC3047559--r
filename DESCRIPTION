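Package: pocketscope
Title: Optical Simulation and Image Analysis for Ball-Lens Phone Microscopes and Slit-Grating Spectrometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for cell-phone-scale optical instruments built
    from a ball-lens microscope attachment and a slit-grating spectrometer tube.
    Provides a sequential geometric ray tracer with first-order and spot-diagram
    metrics (magnification, field of view, numerical aperture, best focus, depth
    of field), sum-modified-Laplacian multifocus image fusion to recover the
    field lost to field curvature, radial (pincushion/barrel) distortion fitting
    and correction, a grating-spectrometer forward model with wavelength
    calibration and spectrum extraction, marker-controlled watershed counting of
    red cells in smear images, and seeded synthetic-fixture generators for every
    input class (resolution targets, aberrated focal stacks, blood smears,
    dispersed slit images).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
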