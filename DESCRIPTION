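Package: soxyprof
Title: SoxY Gene-Family Expansion Profiling in Sulfur-Oxidizing Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies SoxY sulfur-carrier homologs in annotated bacterial
    (meta)genomes with an in-house position-specific scoring profile and
    empirically calibrated e-values, applies length/motif quality filters and
    deduplication, classifies the sulfur-binding "swinging arm" region into
    six named sequence signatures, detects SoxYZ domain fusions, reconstructs
    a neighbor-joining phylogeny with bootstrap support and four-clade
    assignment, summarises per-genome soxY repertoires and sulfur-gene
    presence/absence, and characterises the genomic neighborhood and operon
    architecture of each soxY locus. A seeded synthetic-genome module plants
    ground-truth copies, fusions, decoys and neighborhood layouts so that
    every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    yaml
Config/testthat/edition: 3
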