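Package: spheromorph
Title: Spheroid Image Analysis: Synthetic Scenes, Morphometrics,
    Detection and Segmentation Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A self-contained toolkit for analysing brightfield images of
    multicellular spheroids, as produced by collagen gel contraction
    assays. Generates synthetic spheroid scenes with exact ground truth
    (polygons, binary masks, analytic areas) and contraction time series;
    reads and writes VGG Image Annotator (VIA) polygon annotations;
    computes per-instance morphometrics (area, perimeter, circularity,
    masked mean intensity); runs pluggable spheroid detectors with score
    thresholding, including a classical threshold-and-label baseline; and
    evaluates instance segmentation with COCO-style average precision
    (AP at fixed IoU thresholds, AP@0.75, AP@[0.5:0.95]) for both
    bounding boxes and masks. A batch pipeline ties detection to a
    results CSV and downstream kinetics plots.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
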