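Package: fovalign
Title: Fully Affine Invariant Cross-Session Field-of-View Registration
    for Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Registers cellular-resolution calcium imaging fields of view
    recorded in different sessions, where head re-fixation changes the
    viewing angle in addition to translation and rotation.  Implements
    affine view simulation (tilt/longitude sampling with step 72 degrees
    divided by the tilt) over five interchangeable keypoint backends in
    the SIFT, SURF, AKAZE, BRISK and ORB families, nearest-neighbour
    distance-ratio matching, affine RANSAC, and a reproducibility layer
    that repeats matching and estimation many times and keeps the
    transform minimising the L1 norm of the ROI-mask disagreement.  Also
    provides ROI-mask construction and filtering, Pearson mask
    correlation, Fourier-spectrum sharpness, common-neuron counting,
    CLAHE preprocessing, and a synthetic field-of-view generator used as
    the ground-truth benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
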