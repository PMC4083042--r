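Package: smrnapipe
Title: Differential Small RNA Cluster, miRNA, Methylation and Expression
    Analysis for Mutant vs Wild-Type Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing a mutant and its sibling
    wild type across three regulatory layers: small-RNA abundance in 100 bp
    genomic windows (RPM-normalized, median-based log2 fold values, 4-fold
    differential cluster calling), known and novel miRNA expression
    (isomiR-aware counting, three-pattern classification, stem-loop
    prediction with 5p/3p guide-strand assignment), clone-based bisulfite
    methylation calling in the CG, CHG and CHH cytosine contexts, and
    microarray-style differential expression with chromosomal-distribution
    testing and GO-category proportions.  Includes a synthetic-study
    generator with recorded ground truth so every stage is testable without
    external data, and cross-layer association of small-RNA, methylation
    and expression changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
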