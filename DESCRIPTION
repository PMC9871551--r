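Package: tapline
Title: Tapped-Area Detection and New Tapping Line Location for Rubber Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating the next tapping cut on natural rubber tree
    trunks from images of the tapped area (the bark panel shaved by previous
    harvests). Provides a synthetic trunk/panel scene generator with exact
    ground truth, forward-contracted building blocks of an attention-augmented
    instance-segmentation backbone (aggregated-residual blocks, parallel
    channel/spatial attention, feature-pyramid fusion, anchor generation, a
    fused convolutional/fully-connected mask head and the composite detection
    loss), a deterministic geometric pipeline that refines a rough tapped-area
    mask into the existing tapping line (2x2 difference-operator edge
    detection, non-maximum suppression, hysteresis, lower-left boundary
    tracing, angle and step-distance filtering) and offsets it along the panel
    centre line by the bark-consumption distance to obtain the new tapping
    line (with cubic-polynomial smoothing), plus detection and location
    evaluation metrics (precision/recall/F1, average precision, mask IOU,
    location success rate and pixel location error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
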