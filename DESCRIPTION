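Package: fundusreg
Title: Keypoint-Based Retinal Fundus Image Registration with
    Multi-Positive Contrastive Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature-based registration of color fundus photographs using
    domain-specific keypoints (blood vessel crossovers and bifurcations).
    Keypoints are detected by a fully convolutional network trained with
    heatmap regression, and described by a dense per-pixel descriptor
    network trained with multi-positive multi-negative contrastive
    objectives (supervised contrastive loss and a multi-positive InfoNCE)
    over multiviewed batches of augmented views.  Matching is bidirectional
    and class-restricted, and the projective transform is estimated with
    RANSAC over normalized direct linear transform solutions.  Includes a
    seeded synthetic fundus generator with ground-truth keypoints and
    control points, and registration-score / variable-top-keypoint
    evaluation metrics.  Networks are trained on CPU by a compact
    convolutional engine built on 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
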