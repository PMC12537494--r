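Package: vegsyntax
Title: Masked Language Modelling of Plant Species Assemblages and
    Habitat-Type Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning the compositional 'syntax' of vegetation
    plots. Curates long-format plot observation tables, serialises each plot
    as an abundance-ordered, comma-separated species sentence, trains a small
    bidirectional transformer encoder on a masked-species objective, and
    fine-tunes a classification head that assigns hierarchical EUNIS habitat
    codes to assemblages. Includes naive Bayes co-occurrence and masked
    multilayer-perceptron baselines, plot-count-balanced spatial block
    cross-validation, fill-mask and perplexity evaluation, and a seeded
    synthetic community generator with habitat-specific species pools so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
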