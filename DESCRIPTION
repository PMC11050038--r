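Package: cpbpe
Title: Counter-Propagation/Back-Propagation Neural Networks for QSAR Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage neural-network regression for quantitative
    structure-activity relationship (QSAR) modelling. Stage I trains a
    counter-propagation network (a competitive Kohonen layer with a
    supervised Grossberg output layer) on compounds described by numeric
    molecular descriptors; Stage II extracts the trained neurons as a
    compact surrogate training set and fits a back-propagation
    feed-forward network on them, yielding continuous predictions instead
    of one value per neuron. Includes min-max scaling, self-organizing-map
    based train/test/validation splitting, descriptor reduction by
    variance, correlation and transposed-map grouping, an applicability
    domain based on distances to winning neurons, grid model selection,
    leave-k-out cross-validation, a synthetic-data generator, JSON model
    persistence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
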