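Package: capquant
Title: Prompt-Engineered Instance Segmentation and Capillarization
    Assessment for Basement-Membrane-Stained Myocardium
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weakly supervised instance segmentation of cardiomyocytes and
    capillaries in single-channel immunofluorescence images of basement
    membrane, built around engineered prompts: each detected object's
    bounding box acts as a coarse spatial constraint and a set of
    binary-labeled centroids (the target's own centroid positive, intruding
    neighbours' centroids negative) acts as a fine constraint for a
    pluggable promptable segmentation backend. Includes a deterministic
    reference segmenter, a ground-truth-backed oracle detector, COCO-style
    evaluation (mAP/mAR/F1 over IoU thresholds), capillarization
    measurements (counts, areas, CDFA, CDCA, CCR) with relative-error
    reporting, dataset tooling (Wiener preprocessing, train/val/test
    splits, rotation and mosaic augmentation, COCO/YOLO annotation
    conversion), and a seeded synthetic-scene generator emulating dense
    myocardial cross-sections for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    png,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
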