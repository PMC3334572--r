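Package: fsindel
Title: Functional Effect Prediction for Frameshifting Coding Indels
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether a frameshifting coding insertion/deletion is
    gene-damaging or functionally neutral. Implements transcript coordinate
    mapping, four conservation- and location-based indel features, a published
    four-rule classifier with confidence scores, a C4.5-style decision-tree
    trainer with rule extraction, balanced-sampling repeated cross-validation
    and greedy forward feature selection, dataset-curation filters, a
    compensatory-indel clustering analysis, and a synthetic-data generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    optparse,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
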