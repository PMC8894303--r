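Package: pleuratex
Title: Second-Order Grey-Scale Texture Analysis of Pleural-Line Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative texture analysis of the pleural line in lung
    ultrasound images. Reads 8-bit greyscale frames (DICOM clips, PNG, TIFF),
    restricts analysis to a rectangular or polygonal region of interest around
    the pleural line, computes normalized symmetric grey-level co-occurrence
    matrices over configurable distances and directions, and derives the
    Haralick-style texture features (contrast, cluster shade, cluster
    prominence, entropy, variance, mean, correlation, energy, homogeneity and
    the sum-distribution features) used to discriminate acute respiratory
    distress syndrome from cardiogenic pulmonary edema. Includes per-subject
    aggregation over the twelve standard chest zones, a diagnostic-accuracy
    layer (trapezoidal ROC/AUC, Youden cut-offs, bootstrap AUC comparison,
    stratified k-fold cross-validated classification error, two-way
    absolute-agreement ICC and Cronbach's alpha), and a synthetic module
    providing texture phantoms of the three pleural-line classes and a
    Gaussian per-group feature simulator.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
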