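Package: gaitmat
Title: Footstep Detection, Labeling and Normalization for Pressure-Sensing Walkways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for high-resolution plantar-pressure walkway
    recordings: per-frame footstep detection (thresholding, morphology,
    connected components), SORT-style multi-object tracking into spatiotemporal
    bounding boxes, footstep labeling (walking direction, foot side, incomplete
    and standing flags), robust per-trial outlier scoring, a configurable
    spatial/temporal/amplitude normalization menu, and biomechanical feature
    extraction (vertical ground reaction force, center-of-pressure
    trajectories, peak-pressure images, spatiotemporal gait parameters).
    Includes a parametric walkway simulator with exhaustive ground truth, and
    readers/writers for the NPZ-style and MAT-style tensor containers and CSV
    metadata schemas used by published walkway datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
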