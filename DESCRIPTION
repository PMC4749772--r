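Package: ChemSeg
Title: Rule-Based Offset-Preserving Tokenization for Chemical Named
    Entity Recognition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Offset-preserving, rule-based tokenization of chemical and
    biomedical text for named-entity recognition pipelines. Implements a
    three-step segmentation algorithm (whitespace split; lexicon-driven
    affix split and entity gating; delimiter, digit-run and case-change
    splitting followed by five token merge/repair rules), IOB labeling of
    tokens against gold entity spans given as character offsets,
    segmentation-quality metrics (token count, average token length, and
    the number of incorrectly segmented entities), a 25-feature
    orthographic/word-shape extractor for sequence classifiers, readers
    and writers for abstract/annotation/CoNLL-style files, and a seeded
    synthetic corpus generator that reproduces the segmentation
    phenomena the tokenizer is designed to repair.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    stringi,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: TextMining, Software, Preprocessing
RoxygenNote: 7.3.3
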