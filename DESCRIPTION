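Package: olfadapt
Title: Encoding Models and Slow-Adaptation Analysis for Glomerular Calcium Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing calcium-imaging and firing-rate responses of
    olfactory neurons to pseudorandom binary odor stimuli. Implements
    linear-nonlinear (LN) and nonlinear-linear-nonlinear (NLN) encoding models
    estimated by ridge-regularised reverse correlation, parametric
    exponential-family filter fits with BIC model selection, convolution and
    exact deconvolution of calcium-sensor kinetics, quantification of slow
    multiplicative adaptation (pulse-peak decay fits and the degree-of-adaptation
    statistic), and population-level analyses (PCA over glomerular space,
    linear rescaling of combinatorial representations, and variance coding via
    the coefficient of variation). A synthetic-data generator reproduces the
    generative structure of the experimental design so that every estimator is
    testable by parameter recovery.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
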