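Package: slicemetry
Title: Calibrated Image Morphometry and Lightweight Detection Blocks for
    Herbal Slice Quality Inspection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based quality inspection of herbal decoction
    slices (white peony, Paeoniae Radix Alba). Implements a reference-card
    calibrated morphometry pipeline: Canny edge extraction, contour tracing,
    minimum-area rotated rectangle diameters, pixel-to-millimeter calibration
    against a card of known size, and error/accuracy reporting against caliper
    ground truth. Also provides faithful, testable building blocks of a
    lightweight detection head: reparameterized difference convolutions merged
    into a single equivalent kernel, fine-grained channel attention fusing
    global and local channel statistics, group normalization, a shared
    detection head with per-level scaling, distribution-based bounding-box
    decoding, and precision/recall/mAP evaluation. A deterministic synthetic
    scene and tensor generator supplies ground-truthed fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    withr,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
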