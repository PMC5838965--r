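Package: copdSeq
Title: Targeted RNA-seq Analysis of COPD-Associated Airway Epithelial Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for targeted competitive multiplex PCR amplicon
    RNA-seq of bronchial epithelial cells in COPD case-control studies.
    Converts native versus internal-standard read counts into absolute
    transcript abundance (molecules per million ACTB molecules) with
    stochastic-sampling and representation filters; detects differential
    allelic expression by an F-test comparing inter-individual variance of
    log2 allelic ratios in cDNA heterozygotes against genomic DNA controls;
    builds and compares per-cohort Pearson correlation networks (degree,
    betweenness, harmonic closeness, Wilcoxon rank-sum comparison, Fisher
    r-to-z); fits a shrinkage linear discriminant COPD classifier ranked by
    correlation-adjusted t-scores with pooled cross-validated ROC evaluation;
    provides cohort-level statistics (Fisher exact, Student t, ANCOVA, N-1
    chi-squared enrichment); and implements GWAS-integration utilities
    (regulatory-region restriction, gene intersection, Bonferroni validation,
    D-prime linkage). A synthetic-data generator emulating the study design
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Classification, Network, SNP
RoxygenNote: 7.3.3
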