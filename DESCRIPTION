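Package: stereospine
Title: Markerless Stereo Detection, Matching and Triangulation of Spine
    Surface Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A computer-vision toolkit for markerless tracking of the exposed
    spine in navigated surgery. Pairs of calibrated gray-scale camera views are
    epipolar-rectified, contrast-enhanced (CLAHE) and segmented (Otsu plus
    region growing); anatomical surface features are then detected with one of
    four local invariant detectors (a Hessian-determinant blob detector with
    64-d descriptors, maximally stable extremal regions, FAST segment-test
    corners, and oriented binary ORB features), matched across views by
    normalized cross-correlation or Hamming distance, filtered with the
    epipolar constraint, and triangulated by the midpoint method with the
    length of the shortest segment between back-projected rays reported as the
    triangulation error in millimetres. A synthetic stereo-scene generator with
    exact ground-truth landmarks supports end-to-end metric validation, and
    evaluation helpers compute per-run error summaries, inlier statistics,
    empirical CDFs with distribution-free confidence bands, and per-stage
    timings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
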