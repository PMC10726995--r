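Package: dlsqc
Title: Quality Control of Bacteriophage Preparations from Dynamic Light
    Scattering Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the physical state of bacteriophage
    preparations from dynamic light scattering (DLS) size-intensity spectra.
    Implements the AUC-delta divergence statistic (the L1 distance between
    area-normalized log-binned size spectra), linear calibration of lytic
    titer loss against AUC-delta with prediction intervals and a runs test
    for departure from linearity, threshold logistic classifiers of titer
    loss with odds ratios, Tjur pseudo R-squared and ROC-AUC, and a
    synthetic phage-decay spectrum simulator for end-to-end validation.
    Includes a command-line workflow (compare, train, predict, simulate)
    for calibrating and applying DLS-based bioactivity predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
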