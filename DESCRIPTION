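Package: metamodes
Title: Community Metabolome Fingerprinting from LC-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for turning untargeted LC-MS peak tables from marine
    particulate samples and phytoplankton cultures into comparable metabolite
    fingerprints. Implements feature-level quality control (pooled-sample CV,
    replicate-variability, presence and matrix-blank filters), dereplication of
    isotopologue, adduct and doubly charged satellite features within
    retention-time windows, best-matched internal-standard (B-MIS)
    normalization, k-medoids mode discovery with silhouette-based selection of
    the number of modes, Monte Carlo enrichment of shared metabolites between
    modes of different datasets with metacluster assembly, and absolute
    quantification of identified compounds via response factors. A synthetic
    data generator plants taxon-structured signatures, community gradients,
    instrument drift, satellite features and true concentrations, so that
    every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
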