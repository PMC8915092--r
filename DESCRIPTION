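Package: wristhrv
Title: Heart Rate Variability from Gappy Wrist-Worn Heart Rate Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A validation pipeline for deriving time-domain heart rate
    variability (HRV) indices from the gappy instantaneous heart-rate
    series exported by wrist-worn photoplethysmography devices. Provides
    gap imputation (eleven classical methods benchmarked by masked-slot
    RMSE), model-based correction of wrist heart rate toward a
    chest-strap reference (eight model families with subject-stratified
    splitting and cross-validated grid search), pseudo inter-beat-interval
    reconstruction with Malik/Karlsson/Kamath/Acar artifact rules and
    cubic-spline replacement, the SDNN/RMSSD/pNN50/SDNNi/SDANN indices,
    paired-t agreement statistics, and a seeded synthetic paired-device
    cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pracma,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
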