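Package: methpattern
Title: DNA Methylation Regulator Patterns, Prognostic Signature Scoring, and
    Tumor Microenvironment Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers DNA methylation modification patterns in bulk tumor
    transcriptomes by consensus nonnegative matrix factorization (NMF) on a
    curated 24-gene panel of methylation writers, erasers, and readers;
    derives a prognostic gene signature by moderated F-test differential
    expression followed by univariate Cox screening; summarizes each sample
    with the DNA methylation score (DMS), the sum of its first two principal
    component projections over the signature genes, oriented so that high
    scores track poor prognosis; stratifies patients at a maximally selected
    rank statistics survival cutpoint; and characterizes strata with
    single-sample gene-set enrichment (ssGSEA), preranked GSEA, survival
    statistics, and mutation/copy-number summaries. Ships a synthetic-cohort
    generator with planted pattern, survival, batch, immune, and mutation
    structure so the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    sva,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
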