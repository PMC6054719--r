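Package: xenomark
Title: PDX Methylome Biomarker Discovery from MeDIP-Seq Enrichment
Version: 0.1.0
Authors@R:
    person("Xenomark", "Developers", email = "xenomark@example.org",
           role = c("aut", "cre"))
Description: End-to-end discovery and validation of DNA-methylation therapy
    response biomarkers from patient-derived xenograft (PDX) cohorts profiled
    with MeDIP-seq. Implements absolute methylation (beta) estimation from
    CpG-density-dependent enrichment counts with copy-number and background
    correction, window-wise negative-binomial GLM likelihood-ratio tests for
    differentially methylated regions (group contrasts and quantitative
    therapy-response predictors), large hypomethylated block calling,
    regulatory-region enrichment statistics, promoter methylation versus gene
    expression biomarker triage, and clinical validation statistics (qMSP
    normalization, Mann-Whitney comparison, maximum-accuracy threshold
    classification, Kaplan-Meier and log-rank survival analysis). A synthetic
    data generator emulates the full data structure so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
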