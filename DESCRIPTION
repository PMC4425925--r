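Package: geneRelics
Title: Unitary Gene Loss Discovery and Relic Characterization in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovery and downstream characterization of unitary gene loss
    events in comparative plant genomics. Calls candidate losses of
    long-established genes from ortholog presence/absence over a fixed
    species tree under Dollo parsimony with outgroup constraints, locates
    the mutated remnant locus (relic) by frameshift-aware protein-to-genome
    alignment and detects ORF-disrupting sites, validates relic-lacking
    losses through synteny anchors, and characterizes the outcome: lineage
    gene death rates, GO slim enrichment of lost functions, expression
    vetting of relics against their orthologous counterparts,
    rejected-substitution promoter conservation scoring, and identification
    of expressed relics acting as microRNA decoys (competing endogenous
    RNAs). Includes a synthetic-data generator that emits complete input
    bundles with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
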