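Package: enhancaps
Title: Enhancer Classification from Chaos Game Representation Images
    with a Capsule Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage identification of transcriptional enhancers from DNA
    sequence alone. Sequences are encoded as frequency chaos game
    representation (FCGR) images, in which the cells of an N x N grid count
    k-mer occurrences, and classified with a capsule network whose type-capsule
    lengths give class probabilities via dynamic routing. Stage one separates
    enhancers from non-enhancers; stage two grades predicted enhancers as
    strong or weak. Includes a synthetic benchmark-shaped sequence generator,
    stratified cross-validation with grid search, a metric suite
    (accuracy, sensitivity, specificity, Matthews correlation coefficient,
    AUC), capsule-feature export, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
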