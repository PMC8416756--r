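Package: semseed
Title: Semantic-Seed Bootstrapping of Noun and Verb Categories in
    Child-Directed Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a context-based model of early syntactic category
    acquisition. Starting from a small set of known object- and
    action-referring words (the semantic seed), the model learns two-word
    contexts from part-of-speech tagged child-directed speech and uses
    them to categorize unseen low-frequency words as nouns or verbs, in
    context. Provides corpus ingestion (a token/tag TSV dialect and
    best-effort CHAT transcripts), seed projection, boundary-padded
    trigram/bigram context tables with backoff prediction, a
    frequency-threshold target filter, a context-blind chance baseline,
    hit/miss/false-alarm scoring with precision, recall and an error
    taxonomy, a synthetic child-directed-speech generator with tunable
    context-to-category fidelity, and a cross-validated experiment
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
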