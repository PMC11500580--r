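Package: tespectra
Title: Base-Substitution Spectra and CG-Dinucleotide Composition of
    Transposon-Derived Genes from RNA-seq Consensus Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-gene consensus calling from aligned RNA-seq reads with a
    minimum-fraction rule, the twelve-class base-substitution spectrum of
    each gene's consensus against its reference with the AT>CG / CG>AT
    ratio statistic, CG and GC dinucleotide densities, threshold-driven
    gene-set (Venn) partitioning of transposon-derived genes, CpG-island
    metagene profiles over gene bodies with flanking regions, and a
    synthetic RNA-seq simulator with planted substitution rates so that
    every stage of the pipeline can be verified against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
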