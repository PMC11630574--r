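Package: iaaminer
Title: Mining Bacterial Genomes for Auxin (IAA) Degradation Operons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects iac-like and iad-like indole-3-acetic acid (IAA)
    degradation operons in annotated bacterial genomes by marker-protein
    homology (Smith-Waterman local alignment with identity and coverage
    gates) combined with gene-neighborhood co-localization rules expressed
    in coding-sequence (CDS) ordinal distances. Reconstructs full cluster
    architecture against whole-operon templates, classifies cluster
    completeness, filters metagenome-assembled genomes by quality score,
    and summarises degrader prevalence stratified by habitat or taxonomic
    order. Includes neighbor-joining trees from concatenated cluster
    proteins with Robinson-Foulds comparison against a whole-genome tree,
    quantification of the Salkowski colorimetric IAA-degradation screen,
    and a deterministic synthetic-genome generator that plants operons at
    controlled identity, spacing, order, strand and fragmentation so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
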