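Package: tsgenes
Title: Tissue-Specific Gene and Promoter Discovery from Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery of tissue-specific genes and their
    promoters from bulk FPKM expression atlases. Implements an
    FPKM-threshold specificity caller (target tissue above a high
    threshold, all other tissues below a low threshold), expression-level
    binning, row Z-score transformation with complete-linkage clustering
    for heatmaps, one-sided hypergeometric over-representation testing of
    called gene sets, strand-aware extraction of the sequence upstream of
    each gene's translation start from genome FASTA and GFF3 annotation,
    scanning of promoters for degenerate IUPAC cis-regulatory elements on
    both strands (with a built-in library of eleven tissue-specificity
    elements), and validation of predicted tissue specificity from qPCR
    Ct tables via the 2^-dCt method with per-tissue Student's t-tests.
    Ships a synthetic-data generator that plants known tissue-specific
    genes, undetected genes, promoter motifs, and qPCR fold-changes so
    every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
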