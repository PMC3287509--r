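Package: mlvatyper
Title: Tandem Repeat Discovery and Multiple Locus VNTR Analysis for
    Endosymbiont Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide detection of tandem repeats by seeded wraparound
    dynamic-programming alignment, characterization of VNTR (variable
    number tandem repeat) locus structure (period decomposition,
    internal deletions, direct repeats and palindromic hairpins),
    in-silico PCR allele calling for MLVA (multiple locus VNTR
    analysis) strain typing, and ankyrin repeat-domain architecture
    analysis (repeat-unit detection, transmembrane segments, premature
    stops, insertion elements, repeat-unit phylogenies). Developed for
    Wolbachia-like AT-rich endosymbiont genomes, with a deterministic
    synthetic-sequence generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Phylogenetics
RoxygenNote: 7.3.3
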