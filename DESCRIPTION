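Package: prwfit
Title: Persistent Random Walk Analysis of Cell Migration Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell motility from time-lapse centroid tracks: net
    displacements and mean-squared displacement (MSD) by the method of
    non-overlapping intervals, nonlinear least-squares fitting of the
    two-dimensional persistent random walk (Fuerth) equation to recover
    root-mean-square speed S and persistence time P, and the random motility
    coefficient mu = S^2 P / 2.  Includes an exact Ornstein-Uhlenbeck
    trajectory simulator for validation, readers for ImageJ Manual Tracking
    exports and generic track tables, Transwell and competitive in vivo
    migration quantification, and the accompanying group statistics
    (unpaired t-tests, two-way ANOVA with Bonferroni-adjusted per-lag
    comparisons).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
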