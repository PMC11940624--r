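Package: usradiomics
Title: Ultrasound Radiomics Pipeline for Predicting Pathogenic Variant Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end breast-ultrasound radiomics workflow: tumor and
    peritumoral region-of-interest construction, Mazda-convention texture
    features (first-order histogram, gray-level co-occurrence, run-length,
    causal autoregressive model, Haar wavelet sub-band energies), a
    three-step feature-selection cascade (Mann-Whitney with
    Benjamini-Hochberg control, Spearman redundancy pruning, LASSO logistic
    regression with cross-validation), radiomic-score computation, and
    multi-classifier evaluation with a full diagnostic metric panel.
    Includes a synthetic speckle-lesion cohort generator so every stage is
    testable without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    FNN,
    quadprog,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
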