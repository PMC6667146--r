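Package: dsre
Title: Distant Supervision and Transfer Learning for Biomedical Relation
    Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for augmenting small manually annotated relation-extraction
    corpora with large distantly supervised ones. Labels candidate entity-pair
    instances from a relation knowledge base, reduces distant-supervision label
    noise with closest-pair, trigger-word and high-confidence-pattern
    heuristics, encodes instances as multi-channel token feature matrices, and
    trains piecewise-max-pooling convolutional (PCNN) and bidirectional LSTM
    classifiers, including transfer learning from pretrained models. Ships a
    synthetic corpus generator with controlled noise structure so the whole
    pipeline can be exercised end to end without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
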