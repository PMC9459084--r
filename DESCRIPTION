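Package: pmtox
Title: Spectrum-Effect Modelling of Hepatotoxic Components in Herbal
    Medicine Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stepwise spectrum-effect analysis pipeline for locating
    hepatotoxic components in raw versus processed herbal medicine cohorts,
    built around pseudotargeted (scheduled-MRM) peak-area tables and
    hepatocyte cytotoxicity assays. Provides untargeted differential-feature
    screening (PCA, OPLS-DA, VIP/p/fold-change cascade), four-parameter
    logistic IC50 estimation from plate optical densities, and a
    three-engine consensus of gray relational analysis, single-response
    OPLS regression with VIP and permutation validation, and a
    back-propagation neural network with Garson and mean-impact-value
    sensitivity screening. Includes a synthetic cohort generator with
    planted toxicity markers for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
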