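Package: behavtrack
Title: Animal Location Tracking and Freezing Analysis from Behavior Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable analysis of single-animal behavior videos. Tracks an
    animal's center of mass frame by frame against a pixel-wise median
    reference frame (absolute or signed differencing, percentile thresholding,
    optional prior-position weighting window), converts pixel distances to
    physical units, scores polygonal region-of-interest occupancy, and
    measures freezing by counting Gaussian-filtered changed pixels against a
    calibrated motion threshold with a minimum-duration rule. Includes
    time-binned summaries, batch processing over folders of videos, static
    summary plots, and a synthetic-fixture generator with exact ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
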