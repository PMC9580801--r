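Package: ovmb
Title: Ovine Vaginal Microbiome Community Typing and Inflammation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis workflow for ovine vaginal microbiome (VMB) studies that
    quantify bacterial communities with a custom 48-target qPCR array (46 taxa
    plus the sheep GAPDH and universal 16S controls) and vaginal inflammation
    with a six-cytokine ELISA panel. Provides sample quality gating, standard
    curve conversion of Cq values to genome copies, relative-abundance
    profiles with coverage and Shannon diversity, community-type (CT)
    assignment by biomarker dominance with uncentered-correlation clustering,
    cytokine threshold models for inflamed/normal classification, a
    majority-consensus eubiosis/dysbiosis caller per CT, and the longitudinal
    treatment-effect statistics used in vaginal-irritant safety studies
    (baseline log fold change, normality-gated ANOVA/Wilcoxon comparisons,
    Kolmogorov-Smirnov CT-distribution shifts, per-CT Fisher exact tests with
    Benjamini-Hochberg correction, and a two-part zero/Wilcoxon chi-square
    test for zero-inflated relative abundances). A synthetic-data generator
    reproduces the statistical structure of such studies so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
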