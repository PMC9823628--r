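Package: pearnet
Title: One-Stage CNN-Transformer Detector for In-Field Pear Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a one-stage convolutional pear detector whose path
    aggregation neck is augmented with a transformer encoder, an attentional
    feature-fusion cross-stage-partial block, and cross-scale skip
    connections, together with the EIoU bounding-box regression loss. The
    package ships its own reverse-mode automatic differentiation engine over
    base R arrays, a synthetic orchard-scene generator with YOLO-format
    ground truth (size strata, occlusion, illumination regimes, ground and
    aerial viewpoints), a stochastic-gradient training loop, and a full
    detection evaluation stack (non-maximum suppression, precision, recall,
    F1, AP50 and AP50:95, stratified reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
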