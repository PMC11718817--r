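Package: spheromotion
Title: Motility and Arrest Analysis of Immune-Cell Tracks in Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cytotoxic T lymphocyte and macrophage motility inside
    three-dimensional tumor spheroids from time-lapse 3D cell tracks.
    Classifies cells as spheroid-infiltrating or peripheral against an evolving
    spheroid surface (analytic sphere or watertight triangle mesh), corrects
    rigid stage drift, computes per-track kinematics (instantaneous velocity,
    average speed, track displacement, track length, straightness), arrest
    statistics at a 2 um/min velocity threshold (arrest coefficient, arrest
    durations, boundary-reflected density curves), tumor-rejection readouts
    (spheroid volume and fragment fold changes, apoptosis proximity), and the
    accompanying statistical layer (Grubbs outlier screening, Welch t-tests,
    one-way ANOVA with Tukey HSD, significance stars). Ships a seeded
    agent-based generator of synthetic spheroid cocultures with two-state
    arrest/motile switching for validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
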