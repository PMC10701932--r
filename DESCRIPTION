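Package: cystra
Title: Structure, Variability and Expression of tRNA-Cys Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of tandemly repeated tRNA gene clusters
    in plant genomes, modelled on the Arabidopsis thaliana tRNA-Cys-GCA
    cluster system. Detects tRNA gene clusters from annotations and
    classifies their orientation, decomposes cluster regions into tandem
    repeating units, calls whole-unit and partial structural differences
    between accessions, groups corresponding units by neighbor-joining of
    alignment identities, deduplicates and clusters mature tRNA sequence
    variants, assesses cloverleaf stem mispairing, and quantifies tRNA
    expression from small-RNA sequencing reads (unique-read collapse, TMM
    normalization, local-alignment best-hit assignment with precursor
    discrimination between identical gene copies). Includes seeded
    generators of synthetic multi-accession genomes and read libraries with
    recorded ground truth, Helitron terminal-signal and hairpin scans, and
    in-silico PCR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
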