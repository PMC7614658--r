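Package: crtoptim
Title: Optimal Design of Two-Arm Parallel Cluster Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic power and sample-size machinery for two-arm parallel
    cluster randomized trials with a continuous outcome, allowing unequal
    allocation of clusters and unequal cluster size between arms.
    Provides arm-specific design effects and effective sample sizes,
    closed-form optimal allocation of individuals and clusters under
    heterogeneous intracluster correlation and variance, sample-size
    solvers, rounding of continuous optima to realizable integer designs
    under practical constraints (minimum clusters per arm, fixed or
    maximum cluster size), sensitivity sweeps over plausible parameter
    ranges, and Monte Carlo validation of the analytic formulas from the
    underlying random-effects model. A command-line interface reproduces
    design tables and power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
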