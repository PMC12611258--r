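Package: degoverlap
Title: Overlap and Concordance Analysis of TF-Dependent Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for sets of differential-expression
    result tables, one per transcription-factor (TF) contrast.  Builds
    expressed-gene universes and DEG sets from DESeq2-style tables, tests
    multi-way DEG-set overlap against a Monte Carlo resampling null with
    order-statistic 95% confidence intervals and z-scores, classifies paired
    log2-fold-change scatter points into shared/single/weak categories and
    computes correlation, regression, sign-concordance and nestedness
    summaries, and provides count normalization and transgene expression-ratio
    utilities.  A synthetic-data generator emulates three candidate regimes of
    multi-TF gene regulation (independent, disjoint, constrained) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
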