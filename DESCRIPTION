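Package: kompot
Title: Cluster-Free Differential Abundance and Expression for Multi-Condition Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Kompot", "Developers", email = "kompot@example.org", role = c("aut", "cre"))
Description: Compares single-cell phenotypic manifolds across conditions without
    clustering. Condition-specific Gaussian-process log-density functions are
    estimated from nearest-neighbor distances over a diffusion-map cell-state
    space, yielding per-cell differential-abundance statistics (normalized
    density log-fold change and posterior tail probability). Condition-specific
    Gaussian-process maps from cell state to log-normalized expression yield
    counterfactual expression, per-cell fold changes, and a covariance-aware
    Mahalanobis distance for per-gene differential expression. Includes a
    synthetic-data generator with known ground truth, plain-text readers and
    writers, and a subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
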