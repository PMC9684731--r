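Package: mazephys
Title: Spike-Train, Field-Potential and Radial-Maze Analysis for Rodent
    Hearing-Loss Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combined behavioral and electrophysiological
    studies of adult-onset hearing loss in the rat. Computes inter-spike-interval
    statistics (firing rate, dispersion index, asymmetry index) from sorted single
    units, Welch-periodogram relative band power and magnitude-squared coherence
    for local field potential and electrocorticogram recordings, reference- and
    working-memory error scores for the 4-arm baited 8-arm radial maze, and the
    study-level group statistics (two-sided Mann-Whitney U, two-way
    repeated-measures ANOVA with Bonferroni post-hoc tests, group-mean imputation).
    A seeded synthetic-cohort generator emulates the statistical structure of the
    recordings and maze logs so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
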