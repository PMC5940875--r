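Package: egsvm
Title: Entropy-Gradient SVM Classification of Neck Infrared Thermograms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies frontal-neck infrared thermograms as lymph-node
    metastasis-positive or metastasis-negative using entropy-gradient
    features fed to a class-weighted linear support vector machine.
    Provides thermogram and temperature-matrix input, expanding-window
    entropy-gradient feature extraction with histogram equalization,
    stratified k-fold cross-validation, diagnostic-accuracy statistics
    (sensitivity, specificity, accuracy, predictive values with Wald
    confidence intervals, Youden's index, likelihood ratios, paired
    noninferiority testing), and a synthetic thermogram phantom generator
    for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
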