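Package: meripeaks
Title: Consensus m6A Peak Calling and Differential Methylation for MeRIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A windowed, multi-technique consensus peak caller for MeRIP-seq
    (m6A-seq) data together with the downstream differential-methylation and
    differential-expression statistics. Protein-coding genes are tiled with
    100-bp half-overlapping windows; four per-sample detection techniques
    (Fisher exact enrichment, reads-per-million fold, peak-over-input
    coverage ratios, and a local-Poisson enrichment test) are combined by
    sample-occurrence and technique-consensus filtering into 150-bp peaks
    centered on the maximum of the median IP coverage. Peaks are annotated
    by gene region and RGACW motif content. Differential methylation (IP
    counts over peaks) and differential expression (Input counts over genes)
    use TMM normalization, precision-weighted log-CPM modelling and
    empirical-Bayes moderated t-statistics with batch covariates. A
    self-contained simulator generates IP/Input coverage with spiked
    methylation sites and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    GenomicAlignments,
    limma,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
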