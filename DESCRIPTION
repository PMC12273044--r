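Package: hoxmeth
Title: HOX Cluster Methylation Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for targeted bisulfite methylation analysis of the four
    HOX gene clusters in matched tumour-normal cohorts. Maps CpG calls from
    cytosine coverage files onto gene regions (promoter, exons, introns),
    classifies matched tumour-normal region methylation differences, scans
    for constitutively unmethylated regions (CURs) that are low and invariant
    across all samples and contrast with their flanking loci, evaluates
    locus-specific CpG panels as diagnostic biomarkers via first-principles
    ROC/AUC with bootstrap confidence intervals and a random-forest
    robustness check, detects natural-antisense (NAT) lncRNA-gene pairs, and
    integrates region methylation with upper-quartile-normalized expression
    through tiered Pearson correlation. Ships a beta-binomial synthetic
    cohort generator that emulates the matched-pair study design so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    edgeR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
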