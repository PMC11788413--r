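Package: commassembly
Title: Community Assembly Analysis of Microbial Beta-Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dissecting the drivers of microbial
    beta-diversity along environmental gradients, built around amplicon
    (ASV) count tables, a phylogeny of the taxa, and georeferenced sample
    metadata. Implements distance-decay regressions with slope contrasts,
    the species-pool (gamma-beta) decoupling test by random-sampling
    expectation, phylogenetic and taxonomic null models (betaNTI and
    abundance-based Raup-Crick) with the five-way assembly-process
    classification, random-matrix-theory thresholded co-occurrence
    networks with topological summaries, and multiple regression on
    distance matrices (MRM) to attribute beta-diversity to assembly
    processes, biotic interactions and environmental distances. A
    synthetic-data generator produces transect-structured communities
    assembled under known processes so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    geosphere,
    stats,
    utils
Suggests:
    picante,
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
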