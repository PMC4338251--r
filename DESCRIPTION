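Package: methatlas
Title: Segmentation and Comparative Analysis of Breast Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing whole-genome bisulfite sequencing (WGBS)
    methylomes of normal and neoplastic breast samples. Segments per-CpG
    methylation tracks into hypomethylated regions (HMRs) and partially
    methylated domains (PMDs) with a two-state beta-binomial hidden Markov
    model, builds a merged reference-HMR atlas and clusters it across
    samples (Gower dissimilarity, Ward linkage), classifies HMR width
    expansion and contraction, scores regulatory potential from feature
    overlaps, integrates promoter methylation with expression, and detects
    loss of X-chromosome inactivation in paired tumour-normal cohorts.
    Ships a synthetic-methylome generator with planted truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
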