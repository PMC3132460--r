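Package: subtelcnv
Title: Subtelomeric Copy Number Loss Calling and Case-Control Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-platform copy-number-variation analysis of a repeat-rich
    subtelomeric region containing a reference-assembly gap. Simulates
    case-control array cohorts (sparse screening and dense tiling designs,
    GC bias, batch effects, heterozygous-deletion carriers), normalizes
    log2-ratio matrices (median centering, GC regression, PCA batch
    removal), calls copy-number losses with a Gaussian-mixture screening
    caller plus consecutive-probe constraints and with a tiling-aCGH
    moving-average caller against a normal-panel median - 1 SD envelope
    with low-copy-repeat no-call masking, and tests case-control carrier
    association (exact two-sided Fisher enumeration, Bonferroni
    correction, odds ratio with Woolf confidence interval). Ships a gene
    annotation table for the 4p16.3 subtelomere and tabular/BED reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    IRanges,
    zoo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
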