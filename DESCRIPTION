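Package: coronaEvo
Title: Evolution of Fibrous-Corona Formation Mechanisms and TurboID
    Proximity-Proteomics Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study the evolution of the kinetochore fibrous corona
    and its CENP-E/RZZ-SPINDLY machinery. Implements fragment-aware CAAX
    prenylation-motif detection on predicted proteomes, species-by-trait
    phylogenetic profiling with explicit unknown states, Dollo and
    asymmetric-cost (Sankoff) parsimony reconstruction of trait gains and
    losses on rooted species trees, and a TurboID proximity-biotinylation
    differential-enrichment workflow (peptide/replicate filtering,
    variance-stabilizing normalization, left-shifted Gaussian imputation of
    missing-not-at-random values, per-protein testing and volcano-style hit
    calling). Ships simulators for trait evolution on a species tree, for
    proteomes carrying or lacking C-terminal CAAX motifs (including
    truncated fragments), and for log-intensity tables with planted
    enrichment and intensity-dependent dropout, so that every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
biocViews: Phylogenetics, Proteomics, Software, SequenceMatching
RoxygenNote: 7.3.3
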