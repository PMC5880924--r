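# betadyn

Temporal change in taxonomic and functional beta diversity of lake
assemblages.

`betadyn` is for community ecologists comparing site-by-species
presence/absence surveys from two periods across a set of sites (its design
case: macrophyte assemblages of ~30 floodplain lakes, before vs after
decades of human impact). It measures, for every pair of sites and both
periods:

* **Taxonomic dissimilarity** — Jaccard D = (b+c)/(a+b+c) on shared/unique
  species counts — partitioned into **turnover**
  D_tu = 2·min(b,c)/(a+2·min(b,c)) and **nestedness** D_ne = D − D_tu
  (Sørensen family optional);
* **Functional dissimilarity** — the same partition applied to convex-hull
  volumes in a 3-axis PCoA trait space (a = volume of the hull
  intersection), with **functional richness (FRic)** as the
  pool-standardized hull volume;

then classifies each pair's temporal change as homogenization (ΔD ≤ 0) or
differentiation (ΔD > 0) per facet, models per-species extirpation counts
against the trait axes (Poisson GLM), relates richness and dissimilarity
changes to human-impact covariates (Gaussian GLMs with VIF screening; MRM
and Mantel permutation tests on pair matrices), and tests observed
nestedness against a Monte Carlo null of random regional species loss. A
synthetic-data generator with machine-readable ground truth (30 lakes ×
275-species pool by default) makes the whole chain testable end to end.

## Worked example

```r
library(betadyn)

scen  <- syntheticScenario(seed = 42)   # 30 lakes, 275-species pool
sim   <- simulateScenario(scen)         # paired matrices, traits, covariates
space <- buildFunctionalSpace(traitDistance(encodeTraits(sim$traits)), m = 3)
space
#> FunctionalSpace: 275 species on 3 axes (euclidean distances)
#>   quality: 0.464 of positive-eigenvalue variation retained

tc <- temporalChanges(sim$paired, space)
subset(diversitySummary(tc), index == "total")[, c("facet","period","mean","sd","n")]
#>         facet     period  mean     sd   n
#> 4   taxonomic historical 0.742 0.0699 435
#> 5   taxonomic    current 0.880 0.0724 435
#> 6   taxonomic     change 0.138 0.0774 435
#> 16 functional historical 0.181 0.0788 435
#> 17 functional    current 0.394 0.1962 435
#> 18 functional     change 0.213 0.2014 435

rd <- richnessDecline(sim$paired)
#> richness 65.3 -> 38.2 (decline of means 41.6%; paired t = 8.12, p = 5.9e-09)

nm <- nullNestednessTest(sim$paired, nreps = 999, seed = 1)
#> observed mean nestedness 0.075 vs null 0.081 +- 0.004 (p = 0.947)
```

Reading the numbers: mean pairwise taxonomic dissimilarity rose from 0.742
to 0.880 (mean change +0.138 across the 435 lake pairs), i.e. widespread
taxonomic differentiation, alongside a 41.6% decline in mean per-site
richness. The null-model p of 0.95 says this simulated community's
nestedness is fully explained by random regional loss — by construction,
since the default scenario removes species without a strong global
susceptibility ranking; `nestedLossScenario()` produces the opposite
verdict (see the null-model tests).

`runPipeline(list(seed = 1, outdir = "run"))` executes the whole chain —
functional space, both periods' beta tables, change classification,
extirpation GLM, richness GLMs, MRM/Mantel battery, null model — and writes
a report bundle (CSVs, JSONs, a manifest with every seed and stage timing).

## Package layout

S4 containers (`AssemblageMatrix`, `PairedAssemblages`, `TraitTable`,
`CovariateTable`, `FunctionalSpace`, `SyntheticScenario`) with validity
checks and accessors; analysis results are plain data.frames/lists. See
`vignettes/betadyn-methods.Rmd` for the model, the geometry, the null-model
definition, all tunable parameters and known limitations.
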