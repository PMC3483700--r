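Package: ecknn
Title: Multi-Label Prediction of Enzyme Commission Numbers from Protein
    Signature Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Enzyme Commission (EC) numbers for proteins represented
    as sparse binary vectors of InterPro signature presence, using a
    binary-relevance k-nearest-neighbour classifier with a single shared
    distance computation per query. Models the four-level EC hierarchy
    including incomplete (partial) numbers and active/deleted/transferred
    status remapping; reads and writes sparse attribute-relation files with a
    companion label-hierarchy document; assembles, joins, partitions and
    redundancy-reduces annotated datasets; evaluates predictions with subset
    accuracy and micro-, macro- and example-based metrics under seeded
    cross-evaluation and leave-group-out protocols; and generates synthetic
    annotation databases with long-tail class frequencies for end-to-end
    testing without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    xml2,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
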