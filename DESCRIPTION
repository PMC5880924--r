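Package: betadyn
Title: Temporal Change in Taxonomic and Functional Beta Diversity of
    Lake Macrophyte Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for before/after comparisons of site-by-species
    presence/absence assemblages across floodplain lakes. Builds a functional
    trait space from categorical traits by principal coordinates analysis,
    measures taxonomic and functional richness (convex-hull volume) and
    pairwise dissimilarity partitioned into turnover and nestedness components
    (Jaccard or Sorensen families), classifies temporal homogenization versus
    differentiation, relates extirpation frequency to trait axes with Poisson
    regression, tests human-impact covariates with Mantel and multiple
    regression on distance matrices permutation tests, and compares observed
    nestedness against a Monte Carlo null of random regional species loss.
    Includes a synthetic-data generator with known ground truth emulating the
    study design of 30 lakes and a 275-species pool.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ape,
    geosphere,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'betadyn-package.R'
    'geometry.R'
    'diversity.R'
    'change.R'
    'functional-space.R'
    'utils.R'
    'inference.R'
    'io.R'
    'methods-accessors.R'
    'null-model.R'
    'synthetic.R'
    'pipeline.R'
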