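Package: grnflow
Title: Inflammatory Gene Regulatory Network Inference from Short
    Time-Course Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for inferring transcription-factor-to-gene
    regulatory networks from short time-course transcription profiling of
    cytokine-stimulated cells. Provides noise filtering and gene-level
    consolidation of log2 expression matrices, moderated t-statistics with
    empirical-Bayes variance shrinkage and expected-false-positive control,
    model-profile clustering of short time series with permutation
    significance, position-weight-matrix promoter scanning with min-max
    normalized site scores and z-test motif enrichment, assembly and export
    of bipartite motif-category to gene networks, cross-dataset gene-set
    comparison, hypergeometric term over-representation, comparative-CT
    quantification for qPCR verification data, and a seeded synthetic-data
    generator with ground truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
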