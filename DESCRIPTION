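Package: cwinca
Title: Cumulative-Weight Iterative NCA Feature Selection and Majority-Voting Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for weight-based feature selection and ensemble fusion in
    high-dimensional text classification. Implements neighborhood component
    analysis (NCA) feature weighting with a stochastic-gradient solver,
    cumulative-weight iterative NCA (CWINCA) subset selection driven by 1-NN
    cross-validation loss, a cross-validated classifier bank that records
    out-of-fold prediction vectors, and iterative hybrid majority voting (IHMV)
    that fuses accuracy-ranked prediction vectors at the best-performing
    ensemble depth. Ships a deterministic hashing text-embedding backend and
    synthetic-data generators (planted-feature matrices, prediction ensembles
    with controlled accuracies, toy corpora) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    stats,
    utils,
    e1071,
    rpart,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
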