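Package: prognet
Title: Knockdown-Derived Prognostic Gene Signatures, Survival
    Meta-Analysis and Transcription-Factor Co-Binding Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for deriving poor-prognosis gene signatures from
    transcription-factor knockdown experiments and patient cohorts, and for
    characterising the regulatory genomics behind them. Implements the
    derivation funnel (dual-shRNA differential testing, prognostic log-rank
    screening, two-cell-line intersection, direction and poor-prognosis
    expression filters), meta-gene scoring with Kaplan-Meier, one-sided
    log-rank and binary Cox hazard-ratio statistics, bias-corrected
    standardized-mean-difference (Hedges g*) random-effects meta-analysis of
    tumor-grade association, ChIP-Seq peak-to-promoter annotation,
    genomic-region classification, multi-way peak intersection with a
    permutation overlap test, RNA-Seq-style differential expression with
    Benjamini-Hochberg control, and from-scratch gene-set enrichment analysis
    with phenotype permutation. A seeded synthetic-data module generates
    every input with planted ground truth so each stage is testable against
    a recoverable answer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
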