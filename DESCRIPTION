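Package: phenomark
Title: Marked-Text Phenotype Extraction and HPO Concept Normalization
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for extracting abnormal key findings from short
    dysmorphology physical-examination observations with a large language
    model and normalizing them to Human Phenotype Ontology (HPO) concepts.
    Provides the marked-text span codec (entities delimited with square
    brackets, character offsets recovered by parsing), a three-step
    similarity-based few-shot example selector, chat-prompt construction
    and fine-tuning dataset export, a two-step observed-term/preferred-term
    dictionary normalizer with stemming and case folding, dataset curation
    utilities (span and concept inconsistency detection, concept merges,
    normal-finding removal), evaluation under normalization-only, strict
    and overlapping matching, deterministic mock backends for offline
    testing, and a synthetic corpus generator mirroring the structure of
    real dysmorphology observation datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
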