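Package: circuitry
Title: Signaling Circuit Activities as Mechanism-Based Biomarkers for Drug Sensitivity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms normalized gene-expression matrices into activation
    probabilities of receptor-to-effector signaling circuits and uses those
    probabilities as mechanism-based biomarkers to predict drug sensitivity
    (IC50). Per-feature ON/OFF two-component Gaussian mixtures are calibrated
    on a reference expression compendium; probeset, gene and node activation
    probabilities are combined by probability-of-union; circuit transmission
    probabilities are computed exactly under independent Bernoulli node states
    (with a seeded Monte-Carlo fallback for large circuits); invariant circuits
    are discarded and a discriminative subset is chosen by correlation-based
    feature selection; an epsilon-regression support vector machine with an
    RBF kernel is tuned over a cost/gamma grid by cross-validation. Includes
    differential circuit activation, cross-dataset train/validate pipelines,
    phosphoproteomic concordance classification, and a synthetic-data
    generator producing complete paired train/validate bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
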