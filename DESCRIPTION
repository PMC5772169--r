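Package: subtadr
Title: Insulator-Based Chromatin Sub-Domain Prediction and Enhancer-Gene
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts insulator-delimited chromatin sub-domains (subTADs)
    from CTCF and Cohesin ChIP-seq peak summits collected across many
    samples: consensus summits are merged within a 51 bp window, CTCF
    summits co-bound by Cohesin become insulators, insulators are oriented
    by position weight matrix scanning with a binding-direction fallback,
    and convergently oriented, coverage-balanced insulator pairs within
    1 kb - 1 Mb are paired into non-overlapping domains. On top of the
    domain map the package classifies factor-bound enhancers as repressor,
    neutral or activator from replicate read counts with a trend-moderated
    t statistic, calls regulated genes and trajectory clusters from FPKM
    time courses, and computes the column-scaled association matrix between
    enhancer classes and gene clusters within domains. A synthetic-data
    generator with planted ground truth exercises the whole pipeline
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
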