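Package: durumpanel
Title: Diversity, Linkage Disequilibrium and Marker-Trait Association
    Analysis for Structured Tetraploid Wheat Landrace Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dominant biallelic (DArT-style) marker
    panels genotyped on structured collections of tetraploid wheat
    landraces. Computes Nei gene diversity and the relative diversity
    loss of a subspecies versus the whole collection, scans for markers
    fixed within subspecies, estimates linkage disequilibrium decay with
    permutation significance, an unlinked-pair parametric critical R
    squared and a loess-intersection LD extent, fits the per-environment
    linear mixed model of a modified augmented field design by REML to
    produce accession BLUPs, and runs a structure-corrected general
    linear model association scan with chi-square and regression
    confirmation rules across subspecies and environments. A seeded
    synthetic-collection generator with ground-truth bookkeeping makes
    every stage testable without access to the original genotype matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
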