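Package: metanoise
Title: Stochastic Modelling of Metabolite Heterogeneity in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how stochastic enzyme expression propagates to
    cell-to-cell variability in metabolite levels. Implements an exact
    Gillespie simulator for a metabolic reaction with reversible
    Michaelis-Menten kinetics coupled to the three-stage gene expression
    model (promoter switching, transcription, translation), the analytic
    Poisson Mixture Model (PMM) approximation of the stationary metabolite
    distribution obtained by timescale separation, a finite-state chemical
    master equation solver used as a validation oracle, modality
    classification rules (unimodal/bimodal/multimodal) for discrete
    distributions, and parameter-space sweeps that map switching-induced
    and catalytically-induced bimodality regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
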