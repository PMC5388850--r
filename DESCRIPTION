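Package: qusresponse
Title: Quantitative Ultrasound Features for A Priori Chemotherapy Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting breast tumour response to neoadjuvant
    chemotherapy from pre-treatment quantitative ultrasound (QUS). Implements
    pulse-echo radiofrequency (RF) speckle simulation from point-scatterer
    phantoms, reference-phantom power-spectrum normalization, linear spectral
    fits (midband fit, spectral slope, 0-MHz intercept), Gaussian form-factor
    backscatter fitting (effective scatterer diameter and acoustic
    concentration), spectral-difference attenuation estimation, tumour
    core/margin region geometry with overlapping analysis blocks, parametric
    images and GLCM Haralick textures, patient-level feature tables with
    core-to-margin ratio features, wrapper feature selection with FLD, weighted
    k-NN and RBF-SVM classifiers under leave-one-patient-out cross-validation,
    bootstrap AUC confidence intervals, and Kaplan-Meier / log-rank survival
    stratification by predicted response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    e1071,
    survival,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
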