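Package: vesselcam
Title: Camera-Based Liquid Level and Volume Estimation in Conical Glasses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers liquid level and consumed volume in a conically shaped
    drinking glass from low-resolution images taken by a camera mounted on the
    rim, for fluid-intake monitoring of fluid-restricted patients. Implements
    the full measurement pipeline: edge segmentation (Sobel gradient mask with
    morphological refinement, and a Hessian-based vesselness alternative),
    quadratic curve-scan detection of the liquid-boundary arc, completion of
    the visible arc by point reflection, least-squares conic ellipse fitting
    (plain algebraic, direct ellipse-specific, and Taubin variants),
    pixel-to-metric calibration (quadratic level model and two-term
    exponential area model), conical frustum volume estimation, and
    Bland-Altman agreement statistics. A synthetic scene generator renders
    test images with known ground truth, including controlled Gaussian and
    salt-and-pepper degradation for robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    png,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
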