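Package: cblflux
Title: Constraint-Based Modeling of Inborn Errors of Cobalamin Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inborn errors of cobalamin (vitamin B12)
    metabolism with constraint-based metabolic models. Provides a compact
    linear-programming kernel (flux balance analysis, flux variability
    analysis, gene deletion, medium constraints, flux consistency, metabolite
    production potential), a curated toy fibroblast network carrying an
    explicit cobalamin absorption, transport and cofactor-utilization
    pathway, a knockout battery over the known cobalamin-disease genes with
    affected-flux classification and scenario clustering, transcriptome-driven
    model personalization (FASTCORE-style context extraction, biomass
    gap-filling, eFlux bound scaling), a synthetic expression-cohort
    generator mirroring a methylmalonic-aciduria study design, and
    rank-sum/FDR differential-flux statistics across patient groups and
    symptom strata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
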