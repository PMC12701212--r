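Package: mammodelta
Title: Temporal Subtraction of Sequential Mammograms for Near-Term Mass Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts where a breast mass is likely to appear in the next
    screening round from two temporally sequential digital mammograms.
    Implements deformable (Demons) registration for propagating a
    future-round mass annotation onto the current mammogram, temporal
    subtraction with unsharp-mask enhancement, morphological segmentation of
    candidate regions of interest, a 98-value feature vector per region
    (shape, intensity, first-order statistics, gray-level co-occurrence
    texture, and epidemiological variables), majority-rule merging of eight
    feature-ranking techniques, ADASYN class balancing, and patient-grouped
    cross-validation of ten classifier families including a soft-voting
    ensemble. A reproducible synthetic-cohort generator emulates the cohort
    structure of the original screening study so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    igraph,
    MASS,
    e1071,
    ranger,
    xgboost,
    nnet,
    rpart,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
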