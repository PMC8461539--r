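Package: riskmine
Title: Mining Vaccine Risk Perceptions from Short Social-Media Messages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying health misinformation in
    short social-media messages. Provides rule-based lexical normalization,
    veracity classification (a from-scratch convolutional text classifier with
    multiple kernel widths, a bidirectional LSTM, and SVM / Naive Bayes
    baselines), causal-cue screening and candidate cause/effect phrase
    extraction, Laplace-smoothed pointwise mutual information and its
    normalized form (NPMI) over cause-effect co-occurrence tables,
    embedding-based collapsing of near-duplicate effect phrases via
    density-based clustering, NPMI-based effect ranking with per-category
    cumulative scores, and validation of mined effects against a gold
    risk-perception lexicon using exact / proper / reverse / partial match
    types. Ships a seeded synthetic-corpus generator with analytic oracles so
    every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
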