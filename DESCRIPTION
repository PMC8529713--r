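Package: ontoNorm
Title: Context-Aware Concept Recognition and Normalization for OBO Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Concept recognition for biomedical text in two stages: named
    entity recognition (span detection over BIO token labels, with a
    gazetteer baseline tagger) and named entity normalization (linking each
    mention to an ontology concept). Normalization scores each candidate
    concept by cosine similarities between a sentence embedding of the
    mention and embeddings of the concept's name, definition, and up to
    three hierarchical contexts drawn from is_a/part_of parents, combined
    either as an unweighted sum or by a trained logistic ranker. Includes
    an OBO 1.2 flat-file parser with synonym expansion, brat-style standoff
    annotation I/O, Slot Error Rate and exact-span F1 evaluation, and a
    seeded synthetic ontology/corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
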