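Package: pathpred
Title: Compound-Pathway Association Prediction from Atom-Coloring Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting which biochemical pathways a small molecule
    participates in, following the cross-join pairwise formulation used for
    KEGG-scale pathway annotation. Parses CTAB V2000 molfiles into heavy-atom
    graphs, computes Morgan-style atom-coloring count features, aggregates
    compound features into pathway features over a three-level pathway
    hierarchy with upward annotation propagation, builds the compound-by-
    pathway cross-join pair dataset with de-duplication and size/level
    filters, trains a multi-layer perceptron binary classifier on
    concatenated compound and pathway count vectors, and evaluates it by
    repeated stratified cross-validation with per-compound and per-pathway
    confusion-matrix accumulation and Matthews-correlation-coefficient
    reporting. Includes a synthetic data generator that emits KEGG-like
    molfiles, hierarchies and annotations with a planted, tunable
    compound-class signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
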