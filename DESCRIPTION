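Package: pdacmarkov
Title: Markov Decision Analysis of Surgery-First Versus Neoadjuvant
    Therapy for Potentially Resectable Pancreatic Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic comparison of the surgery-first and
    neoadjuvant therapy pathways for potentially resectable pancreatic
    cancer. Provides meta-analytic synthesis of trial-level inputs
    (Freeman-Tukey double-arcsine pooling of proportions under a
    DerSimonian-Laird random-effects model, and pooled median survival via
    exponential-hazard averaging), a two-strategy decision tree with a
    monthly three-state Markov cohort trace scoring life-months and
    quality-adjusted life-months (QALMs), one- and two-way deterministic
    sensitivity analysis with indifference-threshold root finding,
    probabilistic sensitivity analysis with parametric distribution
    fitting and Anderson-Darling model selection, and a synthetic
    literature-pool generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    fitdistrplus,
    ggplot2
Config/testthat/edition: 3
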