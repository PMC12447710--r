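Package: magicseg
Title: Modality-Agnostic Cascade Segmentation of Cardiac Substructures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single segmentation model for overlapping cardiac
    substructures across several imaging modalities. A U-shaped
    convolutional backbone is replicated into modality-specific encoders
    and group-specific decoders joined by one shared bottleneck, so that
    one network segments twenty substructures organised in four
    mutually-overlapping groups (whole heart; chambers and great vessels;
    coronary arteries and valves; conduction nodes) from simulation CT,
    low-field MR-Linac or cardiac CT angiography input. Includes the full
    training pipeline (hybrid Dice, boundary and cross-entropy loss with
    dual self-distillation, AdamW with a poly learning-rate schedule,
    modality-balanced sampling, pseudo-label expansion), Gaussian-blended
    sliding-window inference, a seeded multi-modality phantom generator,
    and an evaluation suite (Dice, surface Dice, HD95, mean surface
    distance, centerline Dice) with paired and unpaired nonparametric
    method comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
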