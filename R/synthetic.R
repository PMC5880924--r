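#' @include io.R inference.R functional-space.R
NULL

#' Define a synthetic study scenario with known ground truth
#'
#' Parameters emulate the study design the package targets: 30 floodplain
#' lakes, a 275-species regional pool with mean historical site richness
#' 67.5, spatially structured turnover, and human-impact-driven loss
#' averaging 41% of each site's species. All defaults are the emulated study
#' conditions; effect sizes and the seed fix the ground truth exactly.
#'
#' @param n_sites number of lakes.
#' @param pool_size candidate regional pool size.
#' @param mean_richness target mean historical per-site richness.
#' @param occupancy_shape Beta(shape1, shape2) of species occupancy
#'   propensities.
#' @param turnover_strength distance-decay rate of presence probability
#'   (0 = no spatial structure; larger = stronger distance decay of
#'   similarity).
#' @param mean_loss target mean per-occupied-cell removal probability between
#'   periods.
#' @param impact_effects named log-scale coefficients of the standardized
#'   per-site relative covariate changes on the site loss intensity
#'   (names area, tp, secchi, catch).
#' @param trait_effects named list: trait -> named numeric of per-level
#'   log-hazard effects on species extirpation (levels not named get 0).
#' @param axis_effects optional numeric vector of per-PCoA-axis log-hazard
#'   effects (used instead of trait_effects when supplied); the space is
#'   built from the generated traits.
#' @param trait_frequencies named list: trait -> named level sampling
#'   frequencies (must sum to 1); defaults mirror a macrophyte pool where 65%
#'   of species are cosmopolitan and 25% Asian endemic.
#' @param colonization per-cell colonization probability scale (default 0:
#'   current assemblages are exactly nested in historical ones).
#' @param vocab trait vocabulary.
#' @param seed master seed; every generator call derives its randomness from
#'   it.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(n_sites = 30L, pool_size = 275L,
                              mean_richness = 67.5,
                              occupancy_shape = c(0.8, 2.5),
                              turnover_strength = 3,
                              mean_loss = 0.41,
                              impact_effects = c(area = -0.8, tp = 0.3,
                                                 secchi = -0.4, catch = 0.4),
                              trait_effects = list(
                                life_form = c(submerged = 0.5),
                                dispersal_range = c(cosmopolitan = 0.4)),
                              axis_effects = NULL,
                              trait_frequencies = defaultTraitFrequencies(),
                              colonization = 0,
                              vocab = defaultTraitVocabulary(),
                              seed = 1L) {
  new("SyntheticScenario", params = list(
    n_sites = as.integer(n_sites), pool_size = as.integer(pool_size),
    mean_richness = mean_richness, occupancy_shape = occupancy_shape,
    turnover_strength = turnover_strength, mean_loss = mean_loss,
    impact_effects = impact_effects, trait_effects = trait_effects,
    axis_effects = axis_effects, trait_frequencies = trait_frequencies,
    colonization = colonization, vocab = vocab, seed = as.integer(seed)))
}

#' Default trait-level sampling frequencies for the generator
#'
#' Dispersal-range frequencies mirror the emulated macrophyte pool (65%
#' cosmopolitan, 25% Asian endemic, 10% regional + local); the other traits
#' use plausible compositions for a floodplain macrophyte flora.
#'
#' @return named list of named frequency vectors, one per trait.
#' @export
defaultTraitFrequencies <- function() {
  list(
    life_form = c(submerged = 0.45, floating_leaved = 0.15, emergent = 0.30,
                  free_floating = 0.10),
    life_cycle = c(annual = 0.30, perennial = 0.70),
    morphology = c(turion = 0.15, stem = 0.40, rosette = 0.25, leafy = 0.20),
    dispersal_range = c(local = 0.05, regional = 0.05, asian_endemic = 0.25,
                        cosmopolitan = 0.65),
    sexual_propagation = c(monoecism = 0.70, dioecy = 0.30)
  )
}

#' Scenario with strongly nested species loss
#'
#' A metacommunity built to sit in the textbook nested-loss regime: no
#' spatial turnover, a small widespread pool (sites hold most of it), a steep
#' global susceptibility ranking (submerged and cosmopolitan species far more
#' extirpation-prone) and strongly heterogeneous site loss intensities. Under
#' this regime current assemblages form near-perfect nested chains, so the
#' observed mean pairwise nestedness should exceed a random-regional-loss
#' null — the scenario used to exercise the null model's power.
#'
#' @param seed master seed.
#' @param ... further overrides passed to [syntheticScenario()].
#' @return a [SyntheticScenario-class].
#' @export
nestedLossScenario <- function(seed = 1L, ...) {
  syntheticScenario(
    seed = seed, turnover_strength = 0,
    pool_size = 100L, mean_richness = 60, occupancy_shape = c(4, 2),
    trait_effects = list(life_form = c(submerged = 4),
                         dispersal_range = c(cosmopolitan = 3)),
    impact_effects = c(area = -2, tp = 0, secchi = 0, catch = 0),
    mean_loss = 0.45, ...)
}

#' Generate a random species trait table
#'
#' Independent categorical draws per trait with the configured level
#' frequencies.
#'
#' @param poolSize number of species.
#' @param vocab trait vocabulary.
#' @param frequencies named list of level frequencies per trait (defaults to
#'   uniform for traits not listed); each vector must sum to 1.
#' @param seed optional integer seed.
#' @return a [TraitTable-class] with species ids sp001, sp002, ...
#' @export
generateTraits <- function(poolSize, vocab = defaultTraitVocabulary(),
                           frequencies = defaultTraitFrequencies(),
                           seed = NULL) {
  ids <- sprintf("sp%03d", seq_len(poolSize))
  d <- withSeed(seed, {
    cols <- lapply(names(vocab), function(nm) {
      lev <- vocab[[nm]]
      fr <- frequencies[[nm]]
      if (is.null(fr)) fr <- stats::setNames(rep(1 / length(lev), length(lev)),
                                             lev)
      if (!setequal(names(fr), lev))
        stop(sprintf("frequencies for %s must name exactly its levels", nm),
             call. = FALSE)
      if (abs(sum(fr) - 1) > 1e-8)
        stop(sprintf("frequencies for %s must sum to 1", nm), call. = FALSE)
      sample(lev, poolSize, replace = TRUE, prob = fr[lev])
    })
    names(cols) <- names(vocab)
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
  rownames(d) <- ids
  traitTable(d, vocab)
}

#' Generate per-site impact covariates for both periods
#'
#' Historical levels are lognormal around typical floodplain-lake values;
#' current levels apply per-site relative changes drawn to mirror the
#' emulated impacts: area declines (mean -40%), total phosphorus rises,
#' Secchi depth declines, fishery catch rises. Centroids are scattered over
#' the middle-lower floodplain (lon 112-120, lat 28-32).
#'
#' @param n_sites number of lakes (or a [SyntheticScenario-class]).
#' @param seed optional integer seed.
#' @return a [CovariateTable-class] with periods "historical" and "current".
#' @export
generateCovariates <- function(n_sites, seed = NULL) {
  if (is(n_sites, "SyntheticScenario"))
    n_sites <- scenarioParams(n_sites)$n_sites
  sites <- sprintf("L%02d", seq_len(n_sites))
  withSeed(seed, {
    areaH <- stats::rlnorm(n_sites, log(100), 0.9)
    tpH <- stats::rlnorm(n_sites, log(0.05), 0.5)
    secchiH <- stats::rlnorm(n_sites, log(80), 0.4)
    catchH <- stats::rlnorm(n_sites, log(5), 0.6)
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    dArea <- clamp(stats::rnorm(n_sites, -0.40, 0.15), -0.85, 0.20)
    dTp <- exp(stats::rnorm(n_sites, 0.70, 0.40)) - 1
    dSecchi <- clamp(stats::rnorm(n_sites, -0.35, 0.15), -0.80, 0.30)
    dCatch <- exp(stats::rnorm(n_sites, 0.90, 0.50)) - 1
    lon <- stats::runif(n_sites, 112, 120)
    lat <- stats::runif(n_sites, 28, 32)
    covariateTable(data.frame(
      site = rep(sites, 2),
      period = rep(c("historical", "current"), each = n_sites),
      area_km2 = c(areaH, areaH * (1 + dArea)),
      tp_mg_l = c(tpH, tpH * (1 + dTp)),
      secchi_cm = c(secchiH, secchiH * (1 + dSecchi)),
      catch_t_km2 = c(catchH, catchH * (1 + dCatch)),
      lon = rep(lon, 2), lat = rep(lat, 2)))
  })
}

# site positions in km from lon/lat (fast equirectangular projection; the
# generator only needs relative distances)
siteXYFromCovariates <- function(covariates) {
  d <- covariateData(covariates)
  d <- d[!duplicated(d$site), ]
  cbind(x = (d$lon - min(d$lon)) * 85, y = (d$lat - min(d$lat)) * 111) |>
    (\(m) { rownames(m) <- d[!duplicated(d$site), "site"]; m })()
}

#' Generate a historical assemblage matrix with spatial turnover structure
#'
#' Species receive occupancy propensities (Beta draws scaled by a mild
#' dispersal-range multiplier: widespread dispersal means higher occupancy)
#' and niche centers on the site plane; presence probability decays
#' exponentially with the site-to-niche-center distance at rate
#' `turnover_strength`, so expected pairwise dissimilarity increases with
#' inter-site distance (0 = no spatial structure). Probabilities are rescaled
#' so realized mean richness matches the scenario target; empty draws are
#' repaired by forcing each site's highest-probability species present.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param traits a [TraitTable-class] for the pool (occupancy multipliers).
#' @param siteXY optional n_sites x 2 matrix of site coordinates (km);
#'   default positions drawn uniformly on a 200 km square.
#' @param seed optional integer seed.
#' @return an [AssemblageMatrix-class], period "historical".
#' @export
generateHistorical <- function(scenario, traits, siteXY = NULL, seed = NULL) {
  p <- scenarioParams(scenario)
  spp <- speciesNames(traits)
  if (length(spp) != p$pool_size)
    stop("trait table size does not match the scenario pool", call. = FALSE)
  withSeed(seed, {
    if (is.null(siteXY)) {
      siteXY <- cbind(stats::runif(p$n_sites, 0, 200),
                      stats::runif(p$n_sites, 0, 200))
      rownames(siteXY) <- sprintf("L%02d", seq_len(p$n_sites))
    }
    L <- max(stats::dist(siteXY))
    if (L == 0) L <- 1
    q <- stats::rbeta(p$pool_size, p$occupancy_shape[1], p$occupancy_shape[2])
    disp <- as.character(traitData(traits)$dispersal_range)
    mult <- c(local = 0.3, regional = 0.5, asian_endemic = 0.8,
              cosmopolitan = 1.2)[disp]
    q <- q * mult
    niche <- cbind(stats::runif(p$pool_size, min(siteXY[, 1]), max(siteXY[, 1])),
                   stats::runif(p$pool_size, min(siteXY[, 2]), max(siteXY[, 2])))
    dmat <- sqrt(outer(siteXY[, 1], niche[, 1], `-`)^2 +
                 outer(siteXY[, 2], niche[, 2], `-`)^2)  # sites x species
    P <- sweep(exp(-p$turnover_strength * dmat / L), 2, q, `*`)
    f <- p$mean_richness / mean(rowSums(P))
    P <- pmin(f * P, 0.98)
    realized <- mean(rowSums(P))
    if (realized < 0.9 * p$mean_richness)
      warning(sprintf(
        "occupancy saturation: expected mean richness %.1f < target %.1f",
        realized, p$mean_richness), call. = FALSE)
    occ <- matrix(stats::rbinom(length(P), 1, P), nrow(P), ncol(P))
    dimnames(occ) <- list(rownames(siteXY), spp)
    empty <- rowSums(occ) == 0
    if (any(empty))
      for (i in which(empty)) occ[i, which.max(P[i, ])] <- 1
    assemblageMatrix(occ, period = "historical")
  })
}

#' Apply trait- and impact-driven species loss to a historical matrix
#'
#' Per-site loss intensity is log-linear in the z-scored relative covariate
#' changes with the scenario's impact coefficients; per-species extirpation
#' hazard is log-linear in the trait susceptibilities (or in PCoA axis scores
#' when the scenario sets `axis_effects`). The per-occupied-cell removal
#' probability is q = 1 - exp(-b * lambda_site * hazard_species), with the
#' base b calibrated so the mean q over occupied cells equals the scenario's
#' `mean_loss`. Species are removed site-wise by Bernoulli draws; optional
#' colonization adds absent species with probability
#' colonization * occupancy/n_sites (default off, so current assemblages are
#' exactly nested).
#'
#' @param hist historical [AssemblageMatrix-class].
#' @param traits a [TraitTable-class] covering the pool.
#' @param covariates a [CovariateTable-class] covering the sites.
#' @param scenario a [SyntheticScenario-class].
#' @param seed optional integer seed.
#' @param space optional [FunctionalSpace-class] used with `axis_effects`
#'   (default: built from `traits` with the standard one-hot/Euclidean/PCoA
#'   pipeline).
#' @return an [AssemblageMatrix-class], period "current"; attribute
#'   `hazard` carries the per-species log-hazard used (ground truth).
#' @export
applyImpactDrivenLoss <- function(hist, traits, covariates, scenario,
                                  seed = NULL, space = NULL) {
  p <- scenarioParams(scenario)
  occ <- occurrence(hist)
  sites <- rownames(occ); spp <- colnames(occ)
  ch <- impactChanges(covariates, sites = sites)
  z <- scale(as.matrix(ch[, c("area", "tp", "secchi", "catch")]))
  z[is.nan(z)] <- 0
  gamma <- p$impact_effects[c("area", "tp", "secchi", "catch")]
  gamma[is.na(gamma)] <- 0
  logLambda <- drop(z %*% gamma)
  lambda <- exp(logLambda - mean(logLambda))

  if (!is.null(p$axis_effects)) {
    if (is.null(space)) {
      enc <- encodeTraits(traits)
      space <- buildFunctionalSpace(traitDistance(enc),
                                    m = length(p$axis_effects))
    }
    co <- speciesCoordinates(space)[spp, , drop = FALSE]
    eta <- drop(co %*% p$axis_effects)
  } else {
    td <- traitData(traits)[spp, , drop = FALSE]
    eta <- rep(0, length(spp))
    for (nm in names(p$trait_effects)) {
      eff <- p$trait_effects[[nm]]
      lev <- as.character(td[[nm]])
      eta <- eta + ifelse(lev %in% names(eff), eff[lev], 0)
    }
  }
  eta <- eta - mean(eta)
  hazard <- exp(eta)

  curr <- withSeed(seed, {
    if (p$mean_loss <= 0) {
      occ
    } else {
      rate <- outer(lambda, hazard)         # sites x species
      occIdx <- occ > 0
      target <- p$mean_loss
      b <- stats::uniroot(function(b)
        mean(1 - exp(-b * rate[occIdx])) - target,
        lower = 1e-9, upper = 1e4, tol = 1e-10)$root
      q <- 1 - exp(-b * rate)
      removed <- occIdx & matrix(stats::runif(length(q)) < q, nrow(q))
      out <- occ
      out[removed] <- 0
      # richness floor: no lake loses its last species (the emulated surveys
      # record none empty); the least susceptible historical occupant stays
      for (i in which(rowSums(out) == 0)) {
        cand <- which(occIdx[i, ])
        out[i, cand[which.min(q[i, cand])]] <- 1
      }
      if (p$colonization > 0) {
        occup <- colSums(occ)
        pcol <- p$colonization *
          matrix(occup / nrow(occ), nrow(occ), ncol(occ), byrow = TRUE)
        gained <- !occIdx & matrix(stats::runif(length(pcol)) < pcol,
                                   nrow(pcol))
        out[gained] <- 1
      }
      out
    }
  })
  structure(assemblageMatrix(curr, period = "current"),
            hazard = stats::setNames(eta, spp), lambda = lambda)
}

#' Simulate a complete scenario in memory
#'
#' Runs the full generator chain (traits, covariates, historical matrix,
#' impact-driven loss, period alignment) with sub-seeds derived from the
#' scenario's master seed, and collects the ground truth.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with `paired`, `historical`, `current`, `traits`,
#'   `covariates`, `space` (NULL unless axis effects were used),
#'   `ground_truth`.
#' @export
simulateScenario <- function(scenario) {
  p <- scenarioParams(scenario)
  s <- p$seed
  traits <- generateTraits(p$pool_size, p$vocab, p$trait_frequencies,
                           seed = s + 1L)
  covariates <- generateCovariates(p$n_sites, seed = s + 2L)
  hist <- generateHistorical(scenario, traits,
                             siteXY = siteXYFromCovariates(covariates),
                             seed = s + 3L)
  space <- NULL
  if (!is.null(p$axis_effects)) {
    enc <- encodeTraits(traits)
    space <- buildFunctionalSpace(traitDistance(enc),
                                  m = length(p$axis_effects))
  }
  curr <- applyImpactDrivenLoss(hist, traits, covariates, scenario,
                                seed = s + 4L, space = space)
  paired <- suppressWarnings(alignPeriods(hist, curr))
  gt <- list(params = p[setdiff(names(p), "vocab")],
             species_hazard = attr(curr, "hazard"),
             site_lambda = attr(curr, "lambda"),
             realized = list(
               pool_hist = sum(colSums(occurrence(hist)) > 0),
               pool_curr = sum(colSums(occurrence(curr)) > 0),
               mean_richness_hist = mean(rowSums(occurrence(hist))),
               mean_richness_curr = mean(rowSums(occurrence(curr)))))
  list(paired = paired, historical = hist, current = curr, traits = traits,
       covariates = covariates, space = space, ground_truth = gt)
}

#' Write a synthetic scenario bundle to disk
#'
#' Emits the matrices, trait and covariate tables in the package's standard
#' CSV formats plus a machine-readable ground-truth JSON recording every
#' coefficient used. Re-reading the bundle through the readers reproduces the
#' matrices exactly; identical seeds give byte-identical files.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir output directory.
#' @param overwrite allow writing into an existing bundle directory.
#' @return (invisibly) the [simulateScenario()] result, with `paths` added.
#' @export
generateScenarioBundle <- function(scenario, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateScenario(scenario)
  paths <- list(
    historical = file.path(dir, "historical.csv"),
    current = file.path(dir, "current.csv"),
    traits = file.path(dir, "traits.csv"),
    covariates = file.path(dir, "covariates.csv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  writeAssemblageMatrix(sim$historical, paths$historical)
  writeAssemblageMatrix(sim$current, paths$current)
  writeTraitTable(sim$traits, paths$traits)
  writeCovariateTable(sim$covariates, paths$covariates)
  jsonlite::write_json(sim$ground_truth, paths$ground_truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sim$paths <- paths
  invisible(sim)
}
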