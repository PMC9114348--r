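Package: lnckit
Title: Discovery, Characterization and Target Analysis of Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for identifying putative long noncoding
    RNAs (lncRNAs) from an assembled transcriptome and relating them to eyelid
    pigmentation phenotypes: a class-code/structure/expression filter cascade
    with known-lncRNA matching, a three-channel coding-potential consensus
    (ORF, Fickett and hexamer features plus a k-mer channel) with
    cross-validated cutoff selection, sequence characterization including
    minimum-free-energy folding and length-normalized folding energy,
    negative-binomial differential expression between pigmented and
    unpigmented sample groups, cis (genomic window) and trans (hybridization
    energy) target-gene linking gated by co-expression, hypergeometric
    gene-set enrichment, and delta-delta-Ct qPCR validation statistics. A
    synthetic-data module generates transcriptomes, count matrices and qPCR
    tables with planted ground truth so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
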