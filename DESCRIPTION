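Package: autologit
Title: Autologistic Regression for Binary Segmentation of Multi-Band Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for segmenting multi-band (e.g. RGB or hyperspectral)
    images into two classes with the autologistic regression model, a
    spatial extension of logistic regression on the 4-neighbour pixel
    lattice. Provides the joint model in both the {0,1} and {-1,1}
    codings and in standard and centred variants, exact small-lattice
    enumeration oracles, maximum pseudolikelihood estimation, a fast
    two-stage plug-in estimator (logistic regression on balanced pixel
    samples followed by validation-based selection of the spatial
    association parameter), chequerboard Gibbs sampling for marginal
    prediction, triangular-basis additive feature expansion with
    genetic-algorithm subset selection, and a Gaussian Markov random
    field scene simulator for generating labelled synthetic imagery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
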