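Package: cobin
Title: Competitive Read Binning and Variant Trajectories in Two-Species
    Cocultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome sequencing of two-species
    bacterial cocultures. Assigns paired-end reads competitively between two
    cohabiting reference genomes using an alignment score-sum ratio rule,
    estimates pooled (subpopulation) variant allele frequencies across serial
    transfers from CIGAR-aware pileups, annotates coding consequences
    (missense, frameshift) on bacterial gene models, and quantifies species
    abundance from qPCR standard curves and minimum inhibitory concentrations
    from two-fold dilution series. Includes a paired-end coculture read
    simulator with planted variants and full ground truth, a k-mer-seeded
    banded Smith-Waterman aligner, and SAM/VCF/GFF3/FASTA/FASTQ interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    S4Vectors
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
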