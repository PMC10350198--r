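Package: lesionsubtype
Title: Deep-Learning Prediction and Atrophy Subtyping of Post-Stroke Aphasia Severity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for predicting severe post-stroke aphasia from
    template-space brain morphometry and lesion anatomy, and for discovering
    atrophy subtypes from what the classifier attends to. Includes a synthetic
    cohort generator with planted ground truth; ordinal morphometry-map
    preprocessing (lesion-superseding tissue codes, modal downsampling,
    common-field-of-view cropping, scaling); preallocated repeated nested
    stratified cross-validation; a hand-written VGG-style 3D convolutional
    network with warm-restart scheduling and class-weighted training; tuned
    support-vector-machine baselines with optional PCA/ICA reduction; model
    fusion by probability averaging, discriminant stacking and SVMs on
    network-derived features; Grad-CAM++ and Shapley-value saliency
    attribution; consensus clustering of saliency maps with eta-squared
    distance, dip-test screening and PAC model selection; and chi-square
    meta-analytic decoding of exemplar maps against a synthetic study corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    e1071,
    MASS,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
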