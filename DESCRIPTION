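Package: hybcal
Title: Quantitative Calibration of Microarray Hybridization Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-based and model-free information measures for calibrating
    microarray hybridization protocols from a two-sample comparison.  Fits
    per-gene class-conditional Gaussian models and their logistic dual,
    scores competing protocols by naive-Bayes log-likelihood, cross-tested
    generalization accuracy, ROC curves and mutual-information bit rate,
    and checks sample-independence of the resulting ranking by stratified
    random subsampling of zero/low/medium/high differential-expression
    genes.  Includes a temperature-dependent Langmuir adsorption simulator
    with cross-hybridization for validating the measures, and a downstream
    differential-expression impact analysis (dye-swap t tests,
    Benjamini-Hochberg FDR, lost-gene fold-change profiling, Fisher
    enrichment of gene categories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
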