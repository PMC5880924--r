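test_that("trait generation honours level frequencies and the seed", {
  tt <- generateTraits(1000, seed = 4)
  frac <- mean(traitData(tt)$dispersal_range == "cosmopolitan")
  expect_gt(frac, 0.60); expect_lt(frac, 0.70)
  expect_identical(traitData(generateTraits(50, seed = 9)),
                   traitData(generateTraits(50, seed = 9)))
  # single-level trait gives a constant column
  voc <- defaultTraitVocabulary()
  voc$life_cycle <- "perennial"
  tt2 <- generateTraits(20, vocab = voc,
                        frequencies = list(life_cycle = c(perennial = 1)),
                        seed = 1)
  expect_identical(unique(as.character(traitData(tt2)$life_cycle)),
                   "perennial")
  expect_error(
    generateTraits(10, frequencies = list(life_cycle = c(annual = 0.6,
                                                         perennial = 0.6))),
    "sum to 1")
})

test_that("historical matrices hit the richness target and spatial structure", {
  scen <- syntheticScenario(seed = 31)
  sim <- simulateScenario(scen)
  occ <- occurrence(sim$historical)
  expect_identical(dim(occ), c(30L, 275L))
  # mean richness within 10% of the 67.5 target
  expect_lt(abs(mean(rowSums(occ)) - 67.5) / 67.5, 0.10)
  expect_true(all(rowSums(occ) >= 1))

  # turnover strength 0: no relation between dissimilarity and distance
  s0 <- simulateScenario(smallScenario(seed = 5, turnover_strength = 0))
  dm0 <- impactDistanceMatrices(s0$covariates, sites = siteNames(s0$paired))
  b0 <- pairwiseBeta(historical(s0$paired))
  D0 <- matrix(0, 10, 10); D0[lower.tri(D0)] <- b0$tax_total; D0 <- D0 + t(D0)
  sl <- coef(lm(b0$tax_total ~ dm0$geo[lower.tri(dm0$geo)]))[2]
  expect_lt(abs(sl) * mean(dm0$geo), 0.15)  # negligible distance effect

  # strong turnover: Mantel r(D, distance) positive and significant at n = 30
  dm <- impactDistanceMatrices(sim$covariates, sites = siteNames(sim$paired))
  bh <- pairwiseBeta(sim$historical)
  D <- matrix(0, 30, 30); D[lower.tri(D)] <- bh$tax_total; D <- D + t(D)
  mt <- mantelTest(D, dm$geo, nperm = 199, seed = 1, alternative = "greater")
  expect_gt(mt$r, 0)
  expect_lt(mt$p, 0.05)
})

test_that("zero effects leave the historical matrix untouched", {
  scen <- smallScenario(seed = 3, mean_loss = 0,
                        impact_effects = c(area = 0, tp = 0, secchi = 0,
                                           catch = 0),
                        trait_effects = list())
  sim <- simulateScenario(scen)
  expect_identical(occurrence(sim$historical)[, speciesNames(sim$paired)],
                   occurrence(current(sim$paired)))
})

test_that("sites with doubled loss intensity lose more species", {
  # one strong impact coefficient: sites with larger area decline must show
  # more negative richness change (rank correlation)
  cors <- vapply(1:5, function(s) {
    scen <- syntheticScenario(seed = 50 + s,
                              impact_effects = c(area = -1.5, tp = 0,
                                                 secchi = 0, catch = 0))
    sim <- simulateScenario(scen)
    ch <- impactChanges(sim$covariates, sites = siteNames(sim$paired))
    tc <- data.frame(
      loss = rowSums(occurrence(historical(sim$paired))) -
        rowSums(occurrence(current(sim$paired))),
      rich = rowSums(occurrence(historical(sim$paired))))
    cor(ch$area, tc$loss / tc$rich, method = "spearman")
  }, numeric(1))
  # area declines are negative: more decline (smaller delta) -> more loss
  expect_true(all(cors < 0))
  expect_lt(median(cors), -0.4)
})

test_that("trait susceptibility drives extirpation of the targeted trait", {
  scen <- smallScenario(seed = 77, mean_loss = 0.4,
                        trait_effects = list(life_form = c(submerged = 3)))
  sim <- simulateScenario(scen)
  ec <- extirpationCounts(sim$paired)
  lf <- as.character(traitData(sim$traits)[ec$species, "life_form"])
  rate <- ec$loss / pmax(ec$occupancy_hist, 1)
  expect_gt(mean(rate[lf == "submerged"]), mean(rate[lf != "submerged"]))
})

test_that("bundles are deterministic and round-trip through the readers", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  scen <- smallScenario(seed = 12)
  sim <- generateScenarioBundle(scen, d1, overwrite = TRUE)
  generateScenarioBundle(scen, d2, overwrite = TRUE)
  for (f in c("historical.csv", "current.csv", "traits.csv",
              "covariates.csv", "ground_truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  h <- readAssemblageMatrix(file.path(d1, "historical.csv"),
                            period = "historical")
  expect_identical(occurrence(h), occurrence(sim$historical))
  tt <- readTraitTable(file.path(d1, "traits.csv"))
  expect_identical(traitData(tt), traitData(sim$traits))
  cov <- readCovariateTable(file.path(d1, "covariates.csv"))
  expect_s4_class(cov, "CovariateTable")
  # refusing to clobber
  expect_error(generateScenarioBundle(scen, d1), "overwrite")
  # ground truth records the coefficients machine-readably
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_identical(gt$params$n_sites, 10L)
  expect_true(!is.null(gt$params$impact_effects))
})

test_that("default scenario matches the emulated study dimensions", {
  p <- scenarioParams(syntheticScenario())
  expect_identical(p$n_sites, 30L)
  expect_identical(p$pool_size, 275L)
  expect_equal(p$mean_richness, 67.5)
  expect_equal(p$mean_loss, 0.41)
})
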