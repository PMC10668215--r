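Package: wmperturb
Title: Dynamic Luminance Perturbation of Visual Working Memory: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing continuous-report
    working-memory experiments in which memorized items are tagged by
    flickering luminance sequences with fixed circular temporal lags
    (a Leader sequence and one or two time-shifted Follower copies).
    Provides flat-power-spectrum luminance sequence synthesis with circular
    shifting and cross-correlation lag verification; counterbalanced trial
    designs and a generative target/nontarget/guess simulator of orientation
    reports; maximum-likelihood fitting of the three-component von Mises
    mixture model on the doubled orientation circle; and the accompanying
    measurement and inference battery (memory precision as reciprocal
    circular SD, empirical-logit normalized target probability, paired t
    tests with Cohen's d, one-way repeated-measures and mixed-design ANOVA
    with partial eta squared, Holm correction, JZS Bayes factors, and
    a-priori power analysis for paired designs).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
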