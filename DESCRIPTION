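Package: m6Apattern
Title: m6A-Regulator Modification Patterns, Signature Scoring and Survival
    Stratification for Breast-Cancer Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect N6-methyladenosine (m6A) regulator biology in
    bulk tumour transcriptomes: resampling-based consensus clustering of
    samples on the 23 canonical m6A writer/eraser/reader genes, single-sample
    gene-set enrichment (ssGSEA and a GSVA-like ECDF variant) of immune and
    pathway signatures, empirical-Bayes moderated-t differential expression
    between modification patterns, a PCA-based per-sample m6A signature score
    with maximally selected survival cutpoint stratification, and somatic
    mutation burden / copy-number summaries. Ships a synthetic-cohort
    generator with planted cluster, survival and mutation-burden structure so
    the full pipeline is testable end to end without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    mclust,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tools
Suggests:
    limma,
    cluster,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
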