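Package: clinannotate
Title: Dictionary-Based Clinical Text Annotation with Scoring and Context Detection
Version: 0.1.0
Authors@R: person("SIFR", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A standalone annotation engine for clinical and biomedical free
    text. Recognizes occurrences of terminology concepts (preferred labels and
    synonyms) at word boundaries, optionally expands matches along the is_a
    hierarchy, scores annotations with C-Value based termhood measures, detects
    clinical context (negation, experiencer, temporality) with a ConText-style
    trigger/scope algorithm, filters by UMLS Semantic Groups, and exports to
    BRAT standoff, RDF (N-Triples), JSON and TSV. Ships a synthetic corpus
    generator and a micro precision/recall/F1 evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
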