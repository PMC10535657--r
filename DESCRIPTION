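Package: wrkyscan
Title: Gene-Family Characterization Toolkit for Plant WRKY Transcription Factors
Version: 0.1.0
Authors@R:
    person("Winder", "Mendez", email = "wmendez@example.org", role = c("aut", "cre"))
Description: Rule-based identification and classification of WRKY transcription
    factors from genome sequence and annotation, together with the downstream
    analyses typical of a genome-wide gene-family survey: physicochemical
    profiling (molecular weight, isoelectric point, GRAVY, instability index),
    promoter cis-regulatory element scanning against an extensible IUPAC motif
    table, tandem/segmental duplication detection from Smith-Waterman protein
    similarity, Nei-Gojobori (NG86) Ka/Ks estimation with Jukes-Cantor
    correction and divergence-time dating, UPGMA phylogenies with Newick
    output, and FPKM-based expression summaries (expressed-gene sets, Venn
    partitions, log2 matrices, classical MDS). A fully specified synthetic-data
    generator plants family groups, duplicate pairs evolved at controlled
    omega, promoter motifs and count matrices so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
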