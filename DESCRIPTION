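Package: plastidfam
Title: Consensus Prediction of Plastid-Targeted Proteins and Gene-Family
    Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale analysis of chloroplast transit peptide
    prediction across plant proteomes. Implements exhaustive k-of-n consensus
    evaluation of subcellular-targeting predictors with confusion-matrix
    statistics (sensitivity, precision-style specificity, Matthews correlation
    coefficient), reconstruction of confusion matrices from published rounded
    statistics, a modified reciprocal-best-BLAST-hit clustering method with
    intra-species better-hit expansion and plastid-anchored trimming, a
    greedy-centroid clustering method with random reseeding, classification of
    protein families into conserved, semi-conserved, and nascent
    plastid-targeted protein (NPTP) categories, and a synthetic-data generator
    for protein families, targeting truth, predictor calls, and similarity hit
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
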