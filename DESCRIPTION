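Package: reflectimp
Title: Bayesian Modelling of Reflection Impulsivity Task Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing reflection-impulsivity task batteries of the
    kind used in studies of hazardous drinking and other clinical groups. The
    core is a Bayesian ideal-observer model of the beads task with a subjective
    cost of sampling and a softmax cognitive-noise parameter, valued by
    backward induction over the belief lattice, together with hierarchical
    empirical-Bayes expectation-maximization fitting of the two parameters
    under gamma population priors. The package also scores the Information
    Sampling Task (boxes opened, P(correct), points, error classification),
    estimates the hyperbolic discount rate k from the 27-item Monetary Choice
    Questionnaire, runs the standard behavioural group statistics (outlier
    removal, square-root and log10 transforms, pooled t-tests, 2x2 mixed
    ANOVA, Wilcoxon rank-sum, Pearson correlations), and generates fully
    synthetic two-group cohorts with known ground truth for validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
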