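Package: sednet
Title: Community Comparison of Sediment Metagenomes with Split Networks and
    Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for comparing benthic microbial communities
    profiled by shotgun metagenomics across a crossed land-use by rain-event
    sampling design.  Provides score-thresholded lowest-common-ancestor
    taxonomic binning with minimum-support reassignment, 16S rRNA V6 ribotag
    extraction, count-matrix normalization and Bray-Curtis community
    distances, rarefaction and Shannon/evenness diversity summaries,
    neighbor-net circular split networks with non-negative split-weight
    estimation and an explicit splits-graph realization, a read-level
    bootstrap of network reproducibility with Gower-Krzanowski within- and
    between-group distance decomposition, and permutational multivariate
    statistics (mixed-model PERMANOVA with term pooling, PERMDISP, SIMPER and
    a Mantel-type RELATE test).  A synthetic-data module generates every
    pipeline input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    vegan,
    igraph,
    quadprog,
    jsonlite,
    Biostrings,
    IRanges,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ape
Config/testthat/edition: 3
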