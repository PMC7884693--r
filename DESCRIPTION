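Package: photoreca
Title: Photographic-Capture Degradation Simulation and Recalibration
    Evaluation for Chest Radiograph Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the degradation chain of smartphone photographs of
    chest radiographs displayed on computer monitors, with eight seeded
    noise operators (Gaussian noise, saturation tint, overexposure,
    contrast change, motion blur, moire interference synthesised by Radon
    transform round trips, Poisson shot noise, and JPEG compression).
    Calibrates the simulator's ten hyperparameters against a small set of
    reference photographs using complex-wavelet structural similarity and
    the Bhattacharyya distance between intensity histograms, and evaluates
    recalibrated multi-label classifiers with one-versus-all AUROC,
    bootstrap confidence intervals, Welch's t-test, and the intraclass
    correlation coefficient. A synthetic pseudo-radiograph generator with
    planted findings and a monitor-capture simulator make the whole
    pipeline reproducible end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jpeg,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
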