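Package: cohortval
Title: Virtual Cohort Validation and In-Silico Trial Analysis
Version: 0.1.0
Authors@R:
    person("SIMVal", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for validating virtual (synthetic) patient
    cohorts against real cohorts and for analysing validated cohorts in
    in-silico trial designs. Validation covers univariate descriptive
    comparison, Spearman correlation matrices, multivariate comparison via
    Mahalanobis-type quadratic forms against a chi-squared reference, and a
    bootstrap pointwise confidence band on nonparametric density estimates.
    Application covers one-group and two-group designs (chi-square tests,
    t-tests, Kaplan-Meier estimation, log-rank comparison) and two-group
    sample-size estimation that propagates effect-size uncertainty into a
    distribution of required sample sizes and power-shortfall probabilities.
    Includes a synthetic paired-cohort generator with known ground truth, a
    structured report renderer (JSON, Markdown, HTML), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    MASS,
    withr
Config/testthat/edition: 3
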