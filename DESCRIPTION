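Package: pastaclass
Title: CNN-LSTM Classification of Pre-Cooked Pasta from Vis-SWIR Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identification of pre-cooked pasta products in frozen and thawed
    physical states from visible to short-wave infrared (350-2500 nm)
    reflectance spectra. Implements spectrum standardization, principal
    component feature extraction, a systematic stratified 7:3 train/test
    split, a one-dimensional AlexNet-derived convolutional network, a
    long short-term memory classifier, their CNN-LSTM hybrid (all with
    native backpropagation and Adam optimization), classical chemometric
    baselines (KNN, decision tree, naive Bayes, SVM), binary
    classification metrics with macro averaging, a seeded synthetic
    Vis-SWIR reflectance generator emulating the two-product by
    two-state study design, and an end-to-end benchmark pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
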