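Package: respcnn
Title: Respiration Pattern Recognition from Ultra-Wideband Radar with a 1-D
    Convolutional Neural Network
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation, preprocessing and classification of chest-displacement
    respiration signals acquired by impulse ultra-wideband (UWB) radar.
    Provides a seeded five-class respiration simulator (eupnea, bradypnea,
    tachypnea, apnea, body motion) with radar range-bin embedding, scalar
    Kalman-filter denoising and target-bin extraction, 10-second sliding-window
    segmentation with time-shift augmentation, a parameterized 1-D
    convolutional neural network classifier trained with Adam, a two-stage
    hyperparameter search (optimal convolutional-layer depth, then optimal
    parameter ranges over repeated learning), and confusion-matrix evaluation
    against LDA, SVM and MLP baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    data.table,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
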