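Package: clicr
Title: Clustering by Inferred Co-Expression Across Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a query gene set into co-expressed modules (CEMs) by a
    Bayesian partition model with a collapsed Gibbs sampler over a compendium
    of expression datasets, weights each dataset by the posterior probability
    that it supports a module, and expands each module by an integrated
    log-likelihood-ratio scan of the transcriptome against gene-specific
    background co-expression. Includes compendium preprocessing with
    total-variation-distance quality control, a latent-factor synthetic
    compendium generator with planted modules, and a leave-one-out
    cross-validation benchmarking harness with an average-correlation
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
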