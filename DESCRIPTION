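Package: cervimotion
Title: Automated Measurement of Cervical Sagittal Intervertebral Rotational Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for fully automated measurement of sagittal intervertebral
    rotational motion (SIRM) of the cervical spine from flexion, neutral and
    extension lateral radiographs. Implements a 22-landmark vertebral-corner
    annotation scheme, geometric-midplane segmental angle computation for
    C2/3-C6/7, a compact multi-resolution heatmap-regression landmark detector
    trainable on a single CPU, an articulated synthetic-spine simulator with
    known ground-truth rotations and calibrated annotation noise, and the full
    observer-agreement evaluation battery (PCK/MPCK, landmark distance
    reliability, ICC, Pearson correlation, MAE, RMSE, Bland-Altman limits of
    agreement, paired error comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
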