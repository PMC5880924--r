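#' @include synthetic.R change.R null-model.R
NULL

pipelineDefaults <- function() {
  list(
    input = NULL,          # list(historical=, current=, traits=, covariates=)
    simulate = list(),     # syntheticScenario() overrides when input is NULL
    n_axes = 3L,
    encoding = "onehot",
    family = "jaccard",
    include_functional = TRUE,
    nperm = 10000L,
    null_reps = 9999L,
    null_scheme = "uniform",
    null_loss_fraction = NULL,
    mantel_method = "spearman",
    seed = 1L,
    outdir = "betadyn-run",
    digits = 6L
  )
}

#' Run the full analysis pipeline from a single configuration
#'
#' Stages: input (read a bundle or simulate a scenario) -> functional space
#' -> pairwise beta diversity for both periods -> temporal changes and
#' classification -> inference (extirpation Poisson GLM on the trait axes,
#' Gaussian GLMs of richness change on the impact changes, MRM of
#' dissimilarity change on impact distance matrices, Mantel tests) -> null
#' model. Writes a report bundle of CSV/JSON files plus a manifest recording
#' seeds, versions and stage timings. Any stage failure aborts with a
#' stage-labeled error and leaves a FAILED marker next to the partial
#' outputs. Numeric CSV output is written at 6 significant digits.
#'
#' @param config named list overriding the defaults, or a path to a YAML file
#'   with the same structure. Keys: `input` (paths to historical/current
#'   wide CSVs, traits, covariates) or `simulate` (arguments to
#'   [syntheticScenario()]); `n_axes`, `family`, `include_functional`,
#'   `nperm`, `null_reps`, `null_scheme`, `null_loss_fraction`,
#'   `mantel_method`, `seed`, `outdir`.
#' @return (invisibly) a list with every computed object and `outdir`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipelineDefaults(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(cfg$outdir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)), failed)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  sig <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], signif, digits = cfg$digits)
    d
  }
  wcsv <- function(d, file)
    utils::write.csv(sig(as.data.frame(d)), file.path(cfg$outdir, file),
                     row.names = FALSE, quote = FALSE)
  wjson <- function(x, file)
    jsonlite::write_json(x, file.path(cfg$outdir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)

  ## input ----
  dat <- stage("input", {
    if (!is.null(cfg$input)) {
      inp <- cfg$input
      hist <- readAssemblageMatrix(inp$historical, period = "historical")
      curr <- readAssemblageMatrix(inp$current, period = "current")
      traits <- if (!is.null(inp$traits)) readTraitTable(inp$traits) else NULL
      covariates <- if (!is.null(inp$covariates))
        readCovariateTable(inp$covariates) else NULL
      list(paired = alignPeriods(hist, curr), traits = traits,
           covariates = covariates, ground_truth = NULL)
    } else {
      scen <- do.call(syntheticScenario,
                      utils::modifyList(list(seed = cfg$seed), cfg$simulate))
      simulateScenario(scen)
    }
  })
  paired <- dat$paired

  ## functional space ----
  space <- stage("functional_space", {
    if (!cfg$include_functional) NULL else {
      if (is.null(dat$traits))
        stop("functional facet enabled but no trait table supplied")
      tl <- traitlessSpecies(paired, dat$traits)
      if (length(tl))
        stop("species without traits: ",
             paste(utils::head(tl, 5), collapse = ", "))
      enc <- encodeTraits(dat$traits, scheme = cfg$encoding)
      sp <- buildFunctionalSpace(traitDistance(enc), m = cfg$n_axes)
      co <- speciesCoordinates(sp)
      wcsv(data.frame(species = rownames(co), co), "functional_space.csv")
      wcsv(data.frame(axis = seq_along(eigenvalues(sp)),
                      eigenvalue = eigenvalues(sp)), "eigenvalues.csv")
      sp
    }
  })

  ## diversity + temporal change ----
  changes <- stage("temporal_change", {
    tc <- temporalChanges(paired, space, family = cfg$family)
    wcsv(tc$pairs, "changes_pairs.csv")
    wcsv(tc$sites, "changes_sites.csv")
    wcsv(diversitySummary(tc), "table1_summary.csv")
    cls <- classifyChanges(tc)
    wcsv(cls, "table2_classification.csv")
    ext <- extirpationCounts(paired)
    wcsv(ext, "extirpation.csv")
    list(tc = tc, classification = cls, extirpation = ext)
  })
  tc <- changes$tc

  ## inference ----
  inference <- stage("inference", {
    out <- list()
    rd <- richnessDecline(paired)
    occH <- occurrence(historical(paired))
    occC <- occurrence(current(paired))
    out$summary <- c(rd, list(
      pool_hist = sum(colSums(occH) > 0),
      pool_curr = sum(colSums(occC) > 0),
      pool_reduction_pct = poolReduction(sum(colSums(occH) > 0),
                                         sum(colSums(occC) > 0))))
    if (!is.null(space)) {
      ext <- changes$extirpation
      co <- speciesCoordinates(space)[ext$species, , drop = FALSE]
      out$extirpation_glm <- cleanGlm(
        glmFit(ext$loss, as.data.frame(co), family = "poisson"))
    }
    if (!is.null(dat$covariates)) {
      ch <- impactChanges(dat$covariates, sites = siteNames(paired))
      X <- as.data.frame(ch[, c("area", "tp", "secchi", "catch")])
      out$richness_glm_tax <- cleanGlm(
        glmFit(tc$sites$richness_change, X, family = "gaussian"))
      if (!is.null(space))
        out$richness_glm_fun <- cleanGlm(
          glmFit(tc$sites$fric_change, X, family = "gaussian"))
      dm <- impactDistanceMatrices(dat$covariates, sites = siteNames(paired))
      sites <- siteNames(paired)
      respT <- symmetricFromLower(tc$pairs$tax_total_change, sites)
      out$mrm_tax <- cleanMrm(mrm(respT, dm, nperm = cfg$nperm,
                                  seed = cfg$seed + 11L))
      if (!is.null(space)) {
        dFun <- tc$pairs$fun_total_change
        if (anyNA(dFun)) {
          out$mrm_fun <- list(skipped = "degenerate hulls left NA pairs")
        } else {
          respF <- symmetricFromLower(dFun, sites)
          out$mrm_fun <- cleanMrm(mrm(respF, dm, nperm = cfg$nperm,
                                      seed = cfg$seed + 12L))
        }
      }
    }
    out$mantel <- pipelineMantels(tc, siteNames(paired), cfg)
    wjson(out, "inference.json")
    out
  })

  ## null model ----
  nullRes <- stage("null_model", {
    nm <- nullNestednessTest(paired, nreps = cfg$null_reps,
                             seed = cfg$seed + 21L,
                             lossFraction = cfg$null_loss_fraction,
                             scheme = cfg$null_scheme, family = cfg$family)
    wjson(nm[setdiff(names(nm), "null")], "null_model.json")
    nm
  })

  ## manifest ----
  stage("manifest", {
    wjson(list(
      package = as.character(utils::packageVersion("betadyn")),
      r_version = R.version.string,
      seed = cfg$seed,
      derived_seeds = list(mrm_tax = cfg$seed + 11L, mrm_fun = cfg$seed + 12L,
                           mantel = cfg$seed + 13L, null = cfg$seed + 21L),
      config = cfg[setdiff(names(cfg), c("input", "simulate"))],
      timings_sec = timings), "manifest.json")
    if (!is.null(dat$ground_truth)) wjson(dat$ground_truth, "ground_truth.json")
    NULL
  })
  invisible(list(paired = paired, space = space, changes = tc,
                 classification = changes$classification,
                 extirpation = changes$extirpation, inference = inference,
                 null_model = nullRes, ground_truth = dat$ground_truth,
                 outdir = cfg$outdir))
}

# serializable GLM summary (drop the fit object)
cleanGlm <- function(g) g[setdiff(names(g), "fit")]
cleanMrm <- function(m) m

# the standard Mantel battery: congruence of taxonomic and functional change,
# change vs change of nestedness contribution, change vs historical level,
# change vs pairwise species loss
pipelineMantels <- function(tc, sites, cfg) {
  p <- tc$pairs
  mk <- function(v) symmetricFromLower(v, sites)
  runM <- function(a, b, label) {
    if (anyNA(a) || anyNA(b)) return(list(label = label, skipped = "NA pairs"))
    r <- mantelTest(mk(a), mk(b), method = cfg$mantel_method,
                    nperm = cfg$nperm, seed = cfg$seed + 13L)
    list(label = label, r = r$r, p = r$p, nperm = r$nperm)
  }
  out <- list(
    runM(p$tax_total_change, p$tax_nestedness_contribution_change,
         "tax_change_vs_nestedness_contribution_change"),
    runM(p$tax_total_change, p$tax_total_hist, "tax_change_vs_historical"),
    runM(p$pair_species_loss, p$tax_total_change,
         "species_loss_vs_tax_change"))
  if ("fun_total_change" %in% names(p)) {
    out <- c(out, list(
      runM(p$tax_total_change, p$fun_total_change,
           "tax_change_vs_fun_change"),
      runM(p$fun_total_change, p$fun_nestedness_contribution_change,
           "fun_change_vs_nestedness_contribution_change"),
      runM(p$fun_total_change, p$fun_total_hist, "fun_change_vs_historical"),
      runM(p$pair_species_loss, p$fun_total_change,
           "species_loss_vs_fun_change")))
  }
  out
}
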