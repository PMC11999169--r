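Package: kinomepipe
Title: Functional Kinome Profiling from Multi-Exposure Peptide Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for functional kinome
    profiling with multi-exposure peptide arrays (serine/threonine and
    tyrosine kinase chips). Fits per-peptide linear kinetics across
    exposure times, applies signal and linearity quality control,
    computes per-chip log2 fold changes with replicate averaging,
    scores upstream kinase families by random resampling of
    differentially phosphorylated peptides, harmonizes multiple
    upstream-kinase rankers into unified percentile ranks, integrates
    kinase hits over a protein-protein interaction network with a
    prize-collecting Steiner forest, performs gene-set
    over-representation analysis with meta-clustering of significant
    terms, and supplies the summary statistics used for validation.
    A seeded synthetic-array generator with planted kinase activity
    shifts and planted quality-control failures makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
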