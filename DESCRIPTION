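Package: sproutnet
Title: Lightweight Detection of Pea Seed Germination and Vigor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the YOLOv8-Peas lightweight object-detection
    architecture for pea seed germination phenotyping, together with the
    surrounding analysis pipeline: bespoke network blocks (C2f-Ghost, DBS,
    PCC/PDetect, coordinate attention, CARAFE content-aware upsampling),
    analytic parameter and FLOP accounting, label-preserving image
    augmentation, Pascal-VOC/YOLO annotation input and output, a synthetic
    seed-plate image generator, detection metrics (precision, recall, AP,
    mAP, NMS), the Adam optimizer, a desk-scale smoke trainer, and
    germination-rate/germination-index vigor statistics for drought
    screening of pea genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
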