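Package: screenburden
Title: Feature Engineering and Classification for Systematic-Review
    Citation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reducing the burden of screening citations for
    systematic reviews. Reads bibliographic corpora (MEDLINE nbib, RIS,
    JSONL), builds five kinds of feature matrices (stemmed alphabetic
    tokens, unstemmed alphanumeric tokens, controlled-vocabulary indexing
    terms, lexicon-matched review concepts, and LDA topic probabilities
    with Kullback-Leibler divergence features), filters features by
    information gain, trains a complement naive Bayes classifier suited
    to imbalanced data, and evaluates it with a two-reviewer A|B protocol:
    stratified half splits, F-beta-driven grid optimization, screening-
    burden statistics, and Friedman rank comparisons across feature sets.
    Includes synthetic-corpus generators so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
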