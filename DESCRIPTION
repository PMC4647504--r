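Package: nucland
Title: Quantitative Nuclear Architecture Analysis of 3D Chromatin Density Landscapes
Version: 0.1.0
Authors@R: person("Nucland", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of nuclear architecture in 3D
    fluorescence microscopy and 2D transmission electron microscopy images.
    Implements hidden-Markov-random-field chromatin density classification of
    DAPI-stained nuclei into intensity classes via an equal-variance Gaussian
    mixture with an optional Potts spatial prior, marker enrichment and
    depletion profiling across density classes, pixel and spot quantification
    of punctate signals, chromatin/interchromatin interface-length measurement
    on 2D sections, and intensity-weighted radial distance profiling of
    signals relative to the nuclear border. A synthetic nucleus generator
    provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
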