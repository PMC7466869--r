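Package: layerlm
Title: Aligned-Layer Language Models for Annotated-Text Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranked retrieval over documents carrying token-aligned
    annotation layers (lemmas, part-of-speech tags, UMLS-style concept
    and semantic-type identifiers, dependency relations). Implements
    per-layer Dirichlet-smoothed query likelihood scoring, cross-layer
    windowed phrase matching, list and relation query operators, a
    query language with sequential-dependence (Markov random field)
    expansion, TREC-style run and qrels handling with mean average
    precision, and a synthetic generator of layered corpora emulating
    clinical NLP pipeline output for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
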