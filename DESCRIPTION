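Package: phenonest
Title: Layered BiLSTM-CRF Recognition of Nested Phenotype Mentions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-grained phenotype text mining in chronic obstructive
    pulmonary disease (COPD) literature: reading and writing brat-style standoff
    annotations under a 16-category hierarchical scheme that allows entity
    mentions to nest, converting nested mention sets to per-level BIO label
    sequences, a layered bidirectional LSTM-CRF sequence tagger that recognizes
    nested and enclosing mentions by merging detected entity regions into single
    units fed to dynamically stacked layers, strict-match evaluation at
    innermost/outermost/all nesting regimes including inter-annotator agreement
    as micro-averaged F-score, rule-based normalization of mentions to a
    pluggable terminology via six variant-generation techniques, and a seeded
    synthetic nested-corpus generator that makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
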