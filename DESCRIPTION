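Package: needlefinder
Title: Needle Detection and Localization in 3D Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and localizes rigid needles in 3D ultrasound volumes.
    Provides two voxel-level detectors -- a triplanar orthogonal-patch
    convolutional classifier with bootstrap hard-negative resampling, and a
    2.5D thick-slice fully convolutional segmenter with multiplicative
    multi-view fusion -- followed by RANSAC cylinder fitting of the needle
    axis and extraction of the coronal-perpendicular in-plane view.
    Includes a synthetic speckle-phantom generator with ground truth,
    voxel-level and geometric (tip / orientation error) evaluation metrics,
    length-stratified error curves, and a cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
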