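Package: dewindow
Title: Moving-Window Differential Expression Trajectories in Matched
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing blood transcriptome trajectories after a
    diagnosis in nested matched case-control designs with randomized
    follow-up time. Provides a synthetic cohort generator with injectable
    time-localized differential-expression signals, Illumina-style probe
    preprocessing (negative-control normexp background correction,
    offset-log2 transform, quantile normalization, detection-based
    presence filtering, probe-to-gene collapsing, case-control pair
    differencing), an empirical-Bayes moderated paired t-test with
    Benjamini-Hochberg false discovery rate control, moving-window
    differential-expression counting over follow-up time with smoothing
    and stratification, a subsampling test comparing significant-gene
    counts between strata at matched sample size, and gene-set analysis
    via hypergeometric overlap tests and permutation-based preranked
    gene set enrichment on a window-count gene ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    graphics
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
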