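Package: GraphletADP
Title: Predicting Atomic Displacement Parameter Distributions from
    Graphlet Degree Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds atom contact graphs from macromolecular models,
    counts per-atom graphlet orbit degrees (graphlet degree vectors,
    GDVs) for all 15 orbits of the connected 2-4-node graphlets, and
    fits multiple linear regression models that predict the normalized
    distribution of atomic displacement parameters (B values) from
    those purely geometric features.  Includes the single-variable
    contact-number baseline model, shifted-inverse-gamma modelling of
    B-value distributions for quality control, entry-level dataset
    filters, deterministic synthetic-structure generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
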