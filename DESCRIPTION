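Package: mitoflux
Title: Constraint-Based Modelling of Cardiomyocyte Central Metabolism with
    Explicit Proton-Motive-Force Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-compartment (cytosol/mitochondrial matrix) constraint-based
    model of human central metabolism in which the proton motive force (PMF) is
    an explicit pseudo-metabolite: transport steps that affect the membrane
    potential co-transport 0.82 PMF per elementary charge and steps that affect
    the pH gradient 0.18 PMF per proton, the respiratory complexes pump PMF with
    fixed stoichiometry (10 per matrix NADH, 6 per ubiquinol) and the ATP
    synthase consumes 2.7 PMF per ATP. Ships a curated reduced cardiomyocyte
    network with the full respiratory chain (including a reactive-oxygen-species
    branch on complex I), beta-oxidation, TCA cycle, malate-aspartate shuttle,
    ketone-body and amino-acid degradation routes. Provides flux balance
    analysis, flux variability analysis and geometric FBA on a built-in
    bounded-variable simplex solver, model quality-control checks (blocked
    reactions, dead-end metabolites, energy-generating cycles), gene knockouts,
    parameter scans, ATP-yield and disease-simulation protocols, and SBML and
    tabular model I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
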