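Package: morphmod
Title: Phylogenetic Modularity and Integration Analysis of Landmark Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric analysis of evolutionary modularity and
    integration on phylogenies. Provides generalized Procrustes superimposition,
    species mean shapes, principal component ordination with broken-stick axis
    selection and shape backtransforms, phylomorphospace projection,
    multivariate phylogenetic signal (Kmult), covariance-ratio modularity tests
    with model comparison, phylogenetic two-block partial least squares
    integration tests, likelihood-based modular hypothesis selection (EMMLi),
    per-module evolutionary rate ratio tests, penalized-likelihood multirate
    Brownian motion, convergence metrics (C1-C4 and morphospace ellipse
    crossings), and disparity-through-time profiles with burst detection.
    Includes a synthetic-data module that simulates landmark configurations
    evolving by multivariate Brownian motion with block-structured modular
    covariance on pure-birth trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
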