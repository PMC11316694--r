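Package: adiposeg
Title: Volumetric Multi-Contrast MRI Segmentation of Abdominal Adipose Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated segmentation and volume quantification of abdominal
    subcutaneous and visceral adipose tissue (SAT/VAT) on two-point Dixon
    MRI with full field-of-view 3D convolutional neural networks. Provides
    three network families (3D U-Net, attention-based competitive dense 3D
    U-Net, and an nnU-Net-like configuration), class-imbalance-aware soft
    Dice losses including a frequency-balancing boundary-emphasizing
    variant, a synthetic two-point-Dixon abdominal phantom generator with
    exact ground truth, cohort splitting and CPU training, and a complete
    evaluation suite: per-subject Dice, pooled false-positive/negative
    rates, volume quantification with intraclass correlation, longitudinal
    volume-change regression, and the accompanying nonparametric
    statistics layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
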