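Package: crosscell
Title: Cross-Species Comparison of Single-Cell Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing cell-type expression programs across species
    from metacell-level single-cell atlases. Implements iterative comparison
    of co-expression (ICC) to score expression conservation (EC) of ortholog
    pairs and resolve paralogs, EC-weighted cell-type similarity, cell-type
    trees from binarized markers (Log-Det distances, UPGMA, Felsenstein
    bootstrap), co-expression module detection and cross-species module
    integration, Dollo-parsimony reconstruction of expression-character gains
    and losses on a species tree, statistics for intermediate, doublet and
    cycling cells, motif-archetype construction from position probability
    matrices, amino-acid alphabet recoding and neuropeptide-signature
    scanning. Includes synthetic multi-species atlas generators with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ape,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
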