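Package: itercue
Title: Iterative Bayesian Observer Models for Magnitude Reproduction with Symbolic Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how humans combine sensory measurements, prior
    experience, and symbolic pre-cues when reproducing magnitudes such as
    traveled distances. Implements two iterative Bayesian observer models on a
    logarithmic (Weber-Fechner) stimulus scale: a categorical model in which a
    discrete cue signals the stimulus category, and a cue-combination model in
    which the cue acts as an additional noisy sensory channel. Both learn their
    internal states trial by trial with discrete Kalman filters. The package
    generates the blocked and interleaved trial sequences of the underlying
    distance production-reproduction design, simulates synthetic subjects,
    fits model parameters by nonlinear least squares with Jacobian-based
    confidence intervals, and reproduces the behavioral summaries (range
    splitting, overlapping-samples comparison, condition differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
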