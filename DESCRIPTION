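Package: mldppi
Title: Multi-Scale Local Descriptors and Random Forests for
    Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions from primary sequence
    alone. Proteins are encoded with multi-scale local descriptors (MLD):
    each sequence is reduced to a seven-letter physicochemical alphabet,
    split into equal-length segments, and composition, transition and
    distribution (CTD) statistics are computed over every contiguous run
    of segments, yielding a 567-dimensional vector per protein (four
    segments) and 1134 per pair. Pairs are classified with a seedable
    random forest (bagged unpruned Gini trees with a random feature
    subset per split). Includes stratified cross-validation with the
    seven standard confusion-matrix metrics (accuracy, sensitivity,
    specificity, PPV, NPV, F-score, MCC), hyperparameter sweeps, a
    seedable synthetic benchmark generator with planted motif signal,
    ggplot2 visualisations, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
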