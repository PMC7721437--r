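Package: woundwave
Title: Quantification of Epidermal Wound-Response Timelapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the rapid epidermal response to tailfin wounding
    in larval zebrafish from two-channel fluorescence timelapse microscopy.
    Provides a calibrated timelapse container with TIFF input/output, rigid
    drift registration by feature matching with a robust Euclidean fit, sparse
    feature-point velocimetry (Shi-Tomasi corners tracked with a pyramidal
    Kanade-Lucas-Tomasi tracker) reduced to wound-axis speed kymographs,
    reference-normalized delta-F/F0 calcium kymographs, shape-decoupled actin
    intensity dynamics via demons non-rigid registration, height-map cell
    cluster volumetry with Richardson-Lucy deconvolution, trajectory PCA and
    the associated statistics (Welch's ANOVA, Games-Howell post-hoc tests,
    paired t-tests, Cohen's d, bootstrap confidence intervals), a sodium
    indicator saturation-binding calibration, and a series-resistance model of
    transepithelial electrical stimulation. Seeded synthetic-microscopy
    generators with analytic ground truth make the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
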