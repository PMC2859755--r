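Package: seqmrf
Title: Bayesian Markov Random Fields for DNA Signal Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models short DNA signal sequences (transcription factor binding
    sites, splice sites) with Markov random fields in natural (log-linear)
    parameterization, including position weight matrices, weight array
    matrices, higher-order inhomogeneous Markov models, moral Bayesian
    networks, pairwise Markov random fields, and mixtures thereof.  Provides a
    transformed Dirichlet prior that generalizes the product-Dirichlet prior
    to the natural parameterization, BDeu hyper-parameter construction from an
    equivalent sample size, generative (maximum a-posteriori) and
    discriminative (maximum supervised posterior) training under the same
    prior, precision-recall and ROC evaluation, a stratified holdout
    experiment driver, and synthetic benchmark generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Matrix,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
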