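Package: camloc
Title: Weakly Supervised Surgical Tool Localization from Class Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a weakly supervised pipeline for localizing surgical
    tools in laparoscopic video frames using only image-level presence labels.
    A class-weight-balanced multi-label classifier is trained on frame-level
    tool-presence annotations; Grad-CAM attention heat maps are computed from
    the classifier's final spatial feature layer and post-processed into
    bounding boxes via Otsu thresholding, connected-component contour
    extraction, frame-edge and area filtering, and non-maximum suppression.
    Includes a reproducible synthetic laparoscopic-scene generator emulating
    the tool-class imbalance of cholecystectomy video datasets, classification
    metrics (per-class recall, F1, average precision, mAP), IoU-based
    localization matching and F1 evaluation, video-level cross-validation
    splits, and command-line entry points for simulation, training,
    localization, evaluation and visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
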