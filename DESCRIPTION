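Package: thyrocyto
Title: Thyroid Fine-Needle-Aspiration Cytology Image Analysis and Bethesda Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for whole-slide thyroid fine-needle-aspiration
    (FNA) cytology diagnosis. Provides a seeded synthetic cytology generator with
    ground-truth nuclei, cell classes, adequacy and BRAF status; a compact
    pyramid-fusion encoder-decoder network for nuclear segmentation with HSV
    debris rejection and watershed post-processing; nineteen-feature nuclear
    morphometry with a gradient-boosted cell classifier; a large-kernel-attention
    cell classification network with a dual-model agreement gate; aggregation of
    per-cell calls into a 104-attribute slide feature vector; the Bethesda
    category I adequacy rule plus gradient-boosted slide classifiers with a
    cascade BRAF fusion step; and foreground-masked image appearance migration
    for cross-scanner stain normalisation. All stages run offline on synthetic
    fixtures at laptop scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    xgboost,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
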