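Package: phenoner
Title: Hybrid Named-Entity Recognition for Phenotype Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid named-entity recognition system for phenotype candidates
    and five companion entity classes (gene/gene product, disease, organism,
    anatomy, chemical/drug) in biomedical abstracts. Independent labelers --
    per-class dictionary matchers with longest-string matching and plural
    normalization, a modifier-composition rule labeler, and a maximum-entropy
    sequence tagger decoded with beam search -- each propose BIO tag sequences;
    conflicting hypotheses are resolved by a priority list, by maximum-entropy
    re-labeling, or by pairwise learn-to-rank re-ranking of candidates in
    ambiguous segments. Includes BRAT standoff corpus input/output, span-based
    partial and exact matching metrics, cross-validation, unique-mention
    analysis, approximate-randomization significance testing, and a seeded
    synthetic-corpus generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
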