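Package: histoswt
Title: Stationary Wavelet Enhancement and Evaluation for Histopathology
    Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage preprocessing and evaluation toolkit for oral
    squamous cell carcinoma (OSCC) histopathology image analysis. Provides a
    level-1 stationary (undecimated) wavelet transform with a tunable cubic
    detail-coefficient mapping function for classification preprocessing,
    LL-subband extraction with inverted-gray rendering for segmentation
    preprocessing, the seven-transform geometric augmentation protocol with
    stratified 5-fold cross-validation, a Gaussian-process Bayesian optimizer
    for the mapping constants and wavelet choice, one-vs-rest micro/macro
    ROC-AUC and segmentation metric suites, Cohen's kappa, deterministic
    desk-scale reference models, and seeded synthetic generators for graded
    texture images and epithelium/stroma image-mask pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
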