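Package: vmrscan
Title: Detection and Network Analysis of Variably Methylated Regions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies Variably Methylated Regions (VMRs) -- clusters of
    CpG probes with high inter-individual methylation variability -- from
    Illumina-450k-style beta-value matrices using a sex-stratified 1 kb
    sliding-window caller, builds weighted co-methylation networks over VMR
    representative probes (soft-thresholded adjacency, topological overlap,
    dynamic branch decomposition, module eigengenes and membership),
    classifies cis/trans co-regulation, quantifies annotation, transcription
    factor binding site and Gene Ontology enrichments, and measures
    environmental signatures of methylation variability (monozygotic-twin
    discordance, exposure-group tests, isogenic time-course VMR calling).
    Includes a synthetic-data generator emulating the statistical structure
    of population methylation cohorts so every stage is testable without
    controlled-access data.
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
    SummarizedExperiment,
    limma,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
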