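Package: pendiff
Title: Diffusion Model Analysis of Paper-Based Response Time Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-choice response time data collected with
    digital pens in paper-based experiments using the Ratcliff diffusion model.
    Provides Wiener first-passage-time densities and distribution functions
    with across-trial parameter variability, a trial-level simulator, stroke-log
    preprocessing for paper-based lexical decision designs, per-participant
    parameter estimation by Kolmogorov-Smirnov distance minimisation with a
    SIMPLEX search, parametric-bootstrap calibration of the goodness-of-fit
    criterion, synthetic cohort generation for parameter-recovery studies, and
    the group-level statistics (mixed ANOVA, t-tests, partial correlations)
    used in cognitive aging research.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
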