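Package: landres
Title: Landscape Genetics with Optimized Resistance Surfaces, MLPE Models,
    and Gravity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring environmental drivers of animal dispersal
    from individual-based genetic data. Computes microsatellite genetic
    distances (maximum-likelihood pairwise relatedness, Rousset's a-hat,
    proportion of shared alleles), derives terrain surfaces (ruggedness,
    topographic position, kernel point density), parameterizes resistance
    surfaces with Monomolecular and Ricker transformation families,
    computes circuit-theory commute distances and current-flow maps on
    eight-neighbor conductance graphs, fits maximum-likelihood
    population-effects (MLPE) mixed models of pairwise genetic distance,
    optimizes resistance surfaces with a genetic algorithm, performs
    bootstrap AICc model selection with Akaike weights and top-model
    frequencies, and fits singly-constrained gravity models combining
    within-site attraction and between-site resistance. Includes a
    synthetic-data module generating autocorrelated landscapes, genotypes
    structured by a known resistance surface, and gravity networks with
    known effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
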