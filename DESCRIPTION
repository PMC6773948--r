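Package: cellularity
Title: Automated Tumour Cellularity Scoring for Breast Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated estimation of tumour cellularity (TC, the percentage
    of a region occupied by malignant cells) on hematoxylin-and-eosin
    breast-tissue image patches. Implements a hand-engineered pipeline
    (stain separation, nucleus segmentation, SVM cell classification,
    cytoplasm dilation, area fraction and monotone calibration), a
    two-stage cascade (healthy-versus-cancer gate followed by a continuous
    0-100 regressor), whole-slide tiling and heatmap rendering over a
    tumour-bed polygon, and two-way intraclass-correlation agreement
    analysis with range-stratified summaries. A synthetic H&E patch
    generator with per-pixel ground truth makes every stage testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    randomForest,
    mgcv,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
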