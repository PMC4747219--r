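Package: sagprisk
Title: Survival-Based Screening and Risk Stratification for Sense-Antisense Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlation-based screening of sense-antisense gene pairs (SAGPs),
    data-driven grouping of patients by survival on one gene (1-D DDg), a gene
    pair (2-D DDg), or a rotated gene-pair plane (2-D RDDg), synergy- and
    cross-cohort-based signature selection, majority-voting patient
    stratification (WVG), downstream differential expression and gene-set
    enrichment between risk subgroups, promoter/ChIP-peak overlap statistics
    with a bidirectional-promoter doubling rule, SNP-based per-gene copy-number
    summaries, and a synthetic-cohort generator with exported ground truth for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
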