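Package: divrates
Title: Comparative Diversification Rates from Microsatellite Phylogenies and
    Trophic Ecology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing rates of phenotypic and ecological
    diversification between lineages. Builds UPGMA population phylogenies
    from microsatellite genotypes (Nei's standard genetic distance and the
    delta-mu-squared stepwise-mutation distance, with locus bootstrapping),
    fits single- and multi-rate Brownian motion and multi-optimum
    Ornstein-Uhlenbeck trait-evolution models on regime-painted trees,
    and selects among them by parametric-bootstrap (Monte Carlo) likelihood
    ratio tests with explicit power estimates. Companion trophic-ecology
    statistics cover lipid normalisation of delta-13C, two-source trophic
    position, standard ellipse areas (sample, small-sample corrected and
    Bayesian), a Dirichlet-prior Bayesian stable-isotope mixing model,
    stomach-content indices (percent IRI, Schoener proportional similarity)
    and foraging-trial metrics. A forward Wright-Fisher stepwise-mutation
    simulator generates complete synthetic datasets with the same structure
    for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    phangorn,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
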