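Package: cogvec
Title: Bit-Vector Substitution Models for Cognate Data Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents multistate cognate (lexical) presence/absence data as
    bit-vector character matrices with one column per concept, and fits
    continuous-time Markov substitution models tailored to this
    representation (COG and COGs) alongside the standard BIN, MK and GTR
    models. Provides maximum-likelihood tree and parameter inference via
    Felsenstein pruning with nearest-neighbor-interchange search, AIC model
    comparison, a cross-validation diagnostic for overparameterization,
    Shannon-entropy and dataset-shape profiling, and a forward simulator for
    cognate wordlists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
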