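Package: likertfa
Title: Exploratory Factor Analysis for Floor-Effected Likert Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how sample selection shapes the factor
    structure recovered from short ordinal questionnaires with strong floor
    effects, such as disability screeners scored on five-point Likert items.
    Implements two-step maximum-likelihood polychoric correlations, parallel
    analysis with principal-component extraction and the mean-eigenvalue
    retention criterion, minimum-residual factor extraction with oblique
    Geomin rotation, Kaiser-Meyer-Olkin sampling adequacy, simple-random and
    symmetrizing stratified sampling schemes, repeated-sampling retention
    experiments, and a synthetic censored-Likert population generator with a
    calibratable floor effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
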