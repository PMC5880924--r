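test_that("change index is current minus historical and antisymmetric", {
  expect_equal(changeIndex(0.656, 0.736), 0.080)
  expect_equal(changeIndex(0.5, 0.716), 0.216)
  expect_equal(changeIndex(0.595, 0.467), -0.128)
  x <- runif(10); y <- runif(10)
  expect_equal(changeIndex(x, y), -changeIndex(y, x))
})

test_that("pool reduction follows the printed arithmetic", {
  expect_equal(round(poolReduction(275, 240)), 13)
  expect_equal(poolReduction(275, 240), 100 * 35 / 275)
  expect_equal(poolReduction(40, 40), 0)
  expect_equal(poolReduction(40, 0), 100)
  expect_error(poolReduction(0, 0), "positive")
})

test_that("extirpation counts separate loss from colonization", {
  h <- matrix(c(1,1,1,1, 0,0,0,0, 1,0,0,0), 4, 3,
              dimnames = list(paste0("L",1:4), c("sA","sB","sC")))
  cu <- matrix(c(1,0,0,0, 0,0,0,0, 0,1,0,0), 4, 3,
               dimnames = list(paste0("L",1:4), c("sA","sB","sC")))
  p <- suppressWarnings(alignPeriods(assemblageMatrix(h, "historical"),
                                     assemblageMatrix(cu, "current")))
  ec <- extirpationCounts(p)
  ec <- ec[match(c("sA","sC"), ec$species), ]   # sB dropped (absent both)
  expect_identical(ec$loss, c(3, 1))            # 4 sites -> 1 subset; L1 -> L2
  expect_identical(ec$colonization, c(0, 1))
  expect_true(all(ec$loss <= ec$occupancy_hist))
})

test_that("pool-level loss equals species with zero current occupancy", {
  sim <- simulateScenario(smallScenario(seed = 4))
  ec <- extirpationCounts(sim$paired)
  occC <- occurrence(current(sim$paired))
  expect_identical(sum(ec$occupancy_curr == 0), sum(colSums(occC) == 0))
})

test_that("temporal changes carry the eight indices and classifications", {
  sim <- simulateScenario(smallScenario(seed = 2))
  enc <- encodeTraits(sim$traits)
  sp <- buildFunctionalSpace(traitDistance(enc), m = 3)
  tc <- temporalChanges(sim$paired, sp)
  pairs <- tc$pairs
  expect_identical(nrow(pairs), 45L)
  for (nm in c("richness_ratio_tax", "tax_total", "tax_turnover_contribution",
               "tax_nestedness_contribution", "richness_ratio_fun",
               "fun_total", "fun_turnover_contribution",
               "fun_nestedness_contribution")) {
    expect_true(all(paste0(nm, c("_hist", "_curr", "_change")) %in%
                      names(pairs)), info = nm)
    expect_equal(pairs[[paste0(nm, "_change")]],
                 pairs[[paste0(nm, "_curr")]] - pairs[[paste0(nm, "_hist")]])
  }
  expect_true(all(pairs$tax_class %in% c("homogenization", "differentiation")))
  expect_true(all(pairs$cross_class %in% c("TH", "TD")))
  # per-site richness deltas
  expect_equal(tc$sites$richness_change,
               tc$sites$richness_curr - tc$sites$richness_hist)
})

test_that("classification percentages are additive and zeros bin as homogenization", {
  pairs <- data.frame(site_i = "a", site_j = "b",
                      tax_total_change = c(0.1, -0.1, 0.2, 0),
                      tax_turnover_contribution_change = c(0.1, -0.2, 0, 0.3),
                      tax_nestedness_contribution_change = c(-0.1, 0.2, 0, -0.3),
                      tax_class = c("differentiation", "homogenization",
                                    "differentiation", "homogenization"))
  cls <- classifyChanges(list(pairs = pairs))
  tot <- cls[cls$measure == "total", ]
  expect_equal(tot$percent[tot$direction == "differentiation"], 50)
  expect_equal(tot$percent[tot$direction == "homogenization"], 50)
  expect_equal(sum(tot$percent), 100)
  # all-positive deltas: differentiation 100%, homogenization empty
  p2 <- pairs; p2$tax_total_change <- abs(p2$tax_total_change) + 0.01
  cls2 <- classifyChanges(list(pairs = p2))
  tot2 <- cls2[cls2$measure == "total", ]
  expect_equal(tot2$percent[tot2$direction == "differentiation"], 100)
  expect_true(is.na(tot2$mean[tot2$direction == "homogenization"]))
  expect_error(classifyChanges(list(pairs = pairs[0, ])), "empty")
})

test_that("functional cross-classes sum to the functional class totals", {
  sim <- simulateScenario(smallScenario(seed = 8))
  sp <- buildFunctionalSpace(traitDistance(encodeTraits(sim$traits)), m = 3)
  tc <- temporalChanges(sim$paired, sp)
  cls <- classifyChanges(tc)
  fun <- cls[cls$facet == "functional" & cls$measure == "total", ]
  for (dir in unique(fun$direction)) {
    tot <- fun$n[fun$direction == dir & is.na(fun$cross)]
    parts <- sum(fun$n[fun$direction == dir & !is.na(fun$cross)])
    expect_identical(parts, tot)
  }
  # classification cells cover all retained pairs
  tax <- cls[cls$facet == "taxonomic" & cls$measure == "total", ]
  expect_identical(sum(tax$n), sum(!is.na(tc$pairs$tax_total_change)))
})

test_that("pure nested loss moves pairs toward nestedness or lower dissimilarity", {
  sim <- simulateScenario(nestedLossScenario(seed = 3))
  # colonization is off: every current assemblage is a subset of historical
  expect_true(all(occurrence(current(sim$paired)) <=
                    occurrence(historical(sim$paired))))
  tc <- temporalChanges(sim$paired)
  # the disjunction (nestedness contribution up, or dissimilarity down) is
  # not a pairwise theorem (losing a shared species can raise D while
  # flattening the nestedness share) but must dominate under nested loss,
  # and the nestedness contribution must rise in aggregate
  ok <- tc$pairs$tax_nestedness_contribution_change >= -1e-10 |
    tc$pairs$tax_total_change <= 1e-10
  expect_gt(mean(ok, na.rm = TRUE), 0.5)
  expect_gt(mean(tc$pairs$tax_nestedness_contribution_change, na.rm = TRUE), 0)
})

test_that("pairwise species loss supports union and per-site sums", {
  p <- toyPaired()
  # L1 lost s1; L3 lost s4, s5
  u <- pairwiseSpeciesLoss(p, "union")
  s <- pairwiseSpeciesLoss(p, "sum")
  # pair order: (L1,L2), (L1,L3), (L2,L3)
  expect_equal(unname(s), c(1, 3, 2))
  # union: s1 lost from L1 but still absent at L2 currently -> lost from pair
  expect_equal(unname(u[1]), 1)
  expect_true(all(u <= s))
})

test_that("richness decline reports both statistics and the paired t", {
  p <- toyPaired()
  rd <- richnessDecline(p)
  rh <- rowSums(occurrence(historical(p)))
  rc <- rowSums(occurrence(current(p)))
  expect_equal(rd$decline_of_means_pct, 100 * (mean(rh) - mean(rc)) / mean(rh))
  expect_equal(rd$mean_of_site_declines_pct, mean(100 * (rh - rc) / rh))
  expect_equal(rd$df, 2L)
})
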