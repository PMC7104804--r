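Package: bminet
Title: 3D Separable Convolutional Regression and Gradient-Based
    Localization for Volumetric Brain Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a scalar trait (body mass index) from T1-weighted
    structural MR volumes registered to a common space, together with
    scalar covariates (age, sex), using an eight-block 3D spatially
    separable convolutional regression network. Includes a
    regression-adapted 3D Grad-CAM pipeline producing per-subject and
    cohort-average localization maps of the regions driving the
    prediction, a training engine (Adam, snapshot-restore, rigid-body
    augmentation), B-spline volume resampling, a synthetic phantom
    generator with known planted signal for validating prediction and
    localization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
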