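Package: msmtext
Title: Metaphor-Sentiment Modelling of Free Text for Mental-Health Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies metaphorical tokens in free text by best-fit-sense
    selection over word-embedding input/output vectors, extracts
    metaphor-based and sentiment-based document features (sentence
    sentiment-strength scores, emotional fluctuation, five-dimension
    sentic means), rebalances classes with SMOTE, and trains a small
    feedforward network (with logistic-regression and SVM comparators)
    under stratified 10-fold cross-validation to predict binary
    mental-health status labels. Includes generators for synthetic
    embeddings with planted metaphor geometry, toy lexicons and
    ontologies, and two-class document cohorts with controlled effect
    sizes, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    e1071,
    glmnet
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
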