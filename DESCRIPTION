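Package: torporCAGE
Title: Torpor-Specific Promoter Discovery from CAGE Data with Bayesian
    Physiological Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for studying fasting-induced torpor in
    mouse skeletal muscle at promoter resolution. Clusters CAGE-defined
    transcription start sites (CTSS) into tag clusters, computes promoter
    architecture statistics (entropy-based shape index, GC content),
    performs TMM-normalised negative-binomial differential expression with
    exact conditional tests, and classifies promoters as reversible,
    hypometabolic, torpor-specific or deprivation-specific by direction-
    matched set intersection. Adds positional motif enrichment over JASPAR
    position weight matrices, Bayesian circadian baseline modelling of body
    temperature and oxygen consumption for per-timepoint torpor calling,
    and a hierarchical Bayesian model of knockout phenotypes with HPDI
    contrasts. A synthetic-data module generates every input the pipeline
    consumes so the full analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
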