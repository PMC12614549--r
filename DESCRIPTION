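Package: mfcadhere
Title: Biofeedback Adherence Analysis for Minimum Foot Clearance Gait Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing treadmill biofeedback training of foot
    clearance in stroke gait rehabilitation. Computes baseline-versus-session
    similarity and distance profiles (Euclidean, Manhattan, dynamic time
    warping, cross-correlation distance, Pearson correlation, cosine
    similarity) over per-stride Minimum Foot Clearance (MFC) series, predicts
    long-term training outcome from early-session profiles with
    imbalance-aware evaluation protocols (stratified cross-validation,
    repeated undersampling, SMOTE), ranks features by minimum-redundancy
    maximum-relevance with fold-wise majority voting, and tracks inter-session
    adherence with a gait-profile-score style metric (GPS_MFC) and its
    session-to-session variation. Includes a synthetic cohort generator
    emulating improved and unimproved adherence archetypes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rcpp,
    e1071,
    randomForest,
    rpart,
    nnet
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
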