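Package: chemner
Title: Grammar and Dictionary Driven Chemical Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Recognizes chemical entities in plain text or lightly marked-up
    documents using expert-written regular grammars compiled to finite-state
    machines together with curated dictionaries. Every entity found is
    attributable to the named grammar or dictionary that produced it.
    Includes Unicode normalization with offset mapping back to source
    coordinates, weighted-edit spelling correction against automata,
    rule-based entity boundary refinement, abbreviation detection and
    propagation, synonym-list curation filters, and mention-level
    micro-averaged evaluation, plus a synthetic corpus generator so the
    whole pipeline is testable without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
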