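Package: epiABA
Title: Integrative Analysis of ABA-Induced Transcriptional and Epigenetic
    Responses in RdDM-Deficient Maize
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of abscisic acid (ABA) induced
    transcriptional and epigenetic responses in wildtype versus
    RNA-directed-DNA-methylation (RdDM) deficient (mop1-1) maize.
    Implements eight-group classification of differentially expressed genes
    from four genotype-by-treatment pairwise comparisons with overlap and
    contra-regulation accounting; weighted bisulfite methylation ratios with
    coverage and level filters, 100-bp promoter tiling, metagene profiles and
    threshold-based differential-promoter calls; ABRE/coupling-element
    promoter scanning with primary-ABA-target classification and
    gene-regulatory-network propagation to predicted secondary targets;
    24-nt siRNA promoter depletion scoring with miRNA-anchored library
    normalization; and transposable-element superfamily context profiling of
    gene flanks. A seeded synthetic-data generator produces a complete toy
    dataset (genome, annotations, DE statistics, methylome, small-RNA counts,
    regulatory network) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
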