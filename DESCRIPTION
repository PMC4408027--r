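Package: twigwood
Title: Quantitative Wood Anatomy and Trait Correlations for Twig Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying twig wood anatomy from labeled
    cross-section images and for analysing multi-species trait tables.
    Implements grid-point (stereological) estimation of tissue area
    fractions, vessel lumen morphometrics including the hydraulically
    weighted diameter, derived anatomical, physical, leaf and mechanical
    traits, and a normality-gated Pearson/Spearman correlation workflow.
    A synthetic-data module generates labeled wood mosaics with pixel-exact
    ground-truth fractions and species-by-replicate trait tables with
    specified marginals and latent correlation structure, so every stage
    of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    readr,
    jsonlite,
    rlang,
    png,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    readxl,
    EBImage,
    withr
Config/testthat/edition: 3
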