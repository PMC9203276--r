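Package: quantchip
Title: Quantitative Multiplexed ChIP-Seq Scaling and Bivalent-Promoter Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantitative multiplexed
    (MINUTE-style) ChIP-seq and its downstream bivalency analysis. Provides
    barcode demultiplexing with mismatch tolerance, UMI-aware duplicate
    marking, input-normalized read count (INRC) global scaling to 1x reads
    per genome coverage (RPGC), bin/state/promoter/chromosome
    quantification, a negative-binomial Wald differential test with fixed
    size factors, five-class bivalent-promoter annotation with
    class-stratified transcriptional-response statistics, and
    control-anchored single-cell gating rules. A seeded synthetic-data
    generator emulating a naive/primed x EZH2-inhibitor experimental design
    makes every stage testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    S4Vectors,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
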