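Package: pairomics
Title: Integrative Analysis of Paired Tumor Samples Across Copy Number,
    Methylation and Expression Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the integrative analysis of matched two-timepoint
    (e.g. diagnosis/relapse) tumor cohorts profiled on copy-number,
    DNA-methylation and gene-expression microarrays. Provides winsorization
    and exact penalized least-squares segmentation of probe-level log2
    ratios, copy-number aberration calling with marker/length/CNV-mask
    filters, interval arithmetic for paired lesion evolution and genomic
    burden classification, methylation peak counting, differentially
    methylated region detection with sign-flip permutation p-values,
    promoter-window methylation aggregation, the SAM two-class paired
    permutation statistic with q-values, per-pair fold-change concordance
    rules, cross-platform fold-change correlation screens, a DerSimonian-
    Laird random-effects meta-analysis of standardized mean differences,
    and a synthetic paired-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    limma,
    sva,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
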