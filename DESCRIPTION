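Package: emsner
Title: Weakly Supervised Named Entity Recognition for Emergency Medical
    Services Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for extracting clinical procedures, findings and
    medications from telegraphic paramedic free-text case reports without
    hand-labelled training data. Normalizes abbreviation-heavy narratives,
    pseudo-labels them by exact and one-character-deletion fuzzy matching
    against a per-entity synonym lexicon (IOB2 scheme, 17 entities in 3
    categories), trains a BiLSTM-CRF sequence tagger (linear-chain CRF with
    forward-algorithm likelihood and Viterbi decoding, trained with Adam and
    early stopping), and scores predictions with MUC-5 category counts under
    the SemEval-2013 strict and entity-type-matching modes as well as
    O-excluded weighted token metrics. Includes a synthetic paramedic-report
    generator with known gold spans for end-to-end validation, corpus
    utilities (CoNLL-style I/O, deterministic splits, corpus statistics,
    vocabulary, padding, subtoken tag aggregation) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
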