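Package: selscape
Title: Habitat-Selection Analysis with Random Forests on Synthetic Landscapes
Version: 0.1.0
Authors@R:
    person("Landscape", "Ecology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable resource-selection-function (RSF) pipeline for
    categorical landscapes and animal telemetry. Generates synthetic
    five-class landscapes and road networks with controlled composition,
    derives distance-to-edge and moving-window Shannon-evenness covariates,
    simulates telemetry from a known true selection function, delineates
    study areas by buffer-dissolve and 95% kernel home ranges with a direct
    plug-in bandwidth, builds use-availability designs with an available-point
    ratio diagnostic, fits and tunes a subsampling random-forest classifier by
    out-of-bag error, and produces permutation importances, partial-dependence
    curves, a binned two-way interaction ranking with max-drop cutoff,
    leave-one-individual-out AUC cross-validation, and a projected selection
    raster.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
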