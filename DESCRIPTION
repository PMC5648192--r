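Package: gwoelm
Title: Grey-Wolf-Optimized Extreme Learning Machine for Two-Class Clinical Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for two-class prognosis on tabular
    clinical laboratory indices. An extreme learning machine (single hidden
    layer, random input weights, minimum-norm least-squares output weights) is
    wrapped in a binary grey wolf optimization search over feature masks with a
    composite accuracy/parsimony fitness, evaluated under nested stratified
    cross-validation. Includes particle swarm and genetic-algorithm baselines,
    confusion-matrix metrics (accuracy, MCC, sensitivity, specificity),
    univariate group comparisons, ROC/AUC with Hanley-McNeil confidence
    intervals, Fisher linear discriminant analysis, a truncated-normal
    synthetic patient-table generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    readxl
Config/testthat/edition: 3
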