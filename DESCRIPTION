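Package: gaqsar
Title: Genetic-Algorithm QSAR Modelling with a Rigorous Validation Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for small-dataset quantitative structure-activity
    relationship (QSAR) modelling of the kind used in medicinal chemistry:
    descriptor-matrix preprocessing (constant and collinearity filters),
    hierarchical-clustering train/test splits, genetic-algorithm descriptor
    subset selection, multiple linear regression and radial-basis-function
    epsilon support vector regression with leave-one-out tuned
    hyperparameters, a full validation battery (leave-one-out and bootstrap
    Q2, Y-randomization, concordance correlation, modified R2,
    Golbraikh-Tropsha external criteria, variance inflation factors), and
    applicability-domain assessment by leverage (Williams plot) and by
    normalized Euclidean mean distance. A synthetic descriptor-data
    generator with planted ground truth supports recovery testing of the
    whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
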