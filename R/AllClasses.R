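#' @import methods
NULL

#' AssemblageMatrix: binary site-by-species occurrences for one period
#'
#' Container for a presence/absence matrix of one survey period. Rows are
#' sites (lakes), columns species; entries are 0/1. Validity enforces binary
#' entries and unique, non-empty dimnames. Sites with no presences are legal
#' (they arise after alignment or simulated loss) but are reported by
#' [emptySites()].
#'
#' @slot occurrence numeric matrix of 0/1 with site rownames and species
#'   colnames.
#' @slot period single character label for the survey period
#'   (e.g. "historical", "current").
#' @exportClass AssemblageMatrix
setClass("AssemblageMatrix",
  representation(occurrence = "matrix", period = "character"))

setValidity("AssemblageMatrix", function(object) {
  occ <- object@occurrence
  msg <- character()
  if (!is.numeric(occ)) msg <- c(msg, "occurrence must be numeric")
  if (is.null(rownames(occ)) || is.null(colnames(occ)))
    msg <- c(msg, "occurrence needs site rownames and species colnames")
  else {
    if (anyDuplicated(rownames(occ))) msg <- c(msg, "duplicate site ids")
    if (anyDuplicated(colnames(occ))) msg <- c(msg, "duplicate species ids")
  }
  if (is.numeric(occ) && length(occ) && !all(occ %in% c(0, 1)))
    msg <- c(msg, "occurrence entries must be 0 or 1")
  if (length(object@period) != 1L) msg <- c(msg, "period must be length 1")
  if (length(msg)) msg else TRUE
})

#' TraitTable: categorical trait levels per species
#'
#' One row per species, one factor column per trait. The vocabulary slot maps
#' each trait name to its allowed levels; validity checks every assignment
#' against it and forbids missing cells.
#'
#' @slot traits data.frame of factors, rownames are species ids.
#' @slot vocabulary named list, trait name -> character vector of levels.
#' @exportClass TraitTable
setClass("TraitTable",
  representation(traits = "data.frame", vocabulary = "list"))

setValidity("TraitTable", function(object) {
  tr <- object@traits
  voc <- object@vocabulary
  msg <- character()
  if (!identical(sort(names(tr)), sort(names(voc))))
    msg <- c(msg, "trait columns must match vocabulary names")
  if (anyDuplicated(rownames(tr))) msg <- c(msg, "duplicate species ids")
  for (nm in intersect(names(tr), names(voc))) {
    v <- as.character(tr[[nm]])
    if (anyNA(v)) msg <- c(msg, sprintf("missing %s level", nm))
    bad <- setdiff(unique(v[!is.na(v)]), voc[[nm]])
    if (length(bad))
      msg <- c(msg, sprintf("unknown %s level(s): %s", nm,
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' CovariateTable: per-site, per-period human-impact covariates
#'
#' Lake surface area (km^2), total phosphorus (mg/L), Secchi depth (cm) and
#' fishery annual catch (tons/km^2) for both periods, plus lake centroid
#' longitude/latitude in decimal degrees. Physical quantities must be
#' strictly positive and every site needs both periods.
#'
#' @slot data data.frame with columns site, period, area_km2, tp_mg_l,
#'   secchi_cm, catch_t_km2, lon, lat.
#' @exportClass CovariateTable
setClass("CovariateTable", representation(data = "data.frame"))

covariateNumericCols <- c("area_km2", "tp_mg_l", "secchi_cm", "catch_t_km2")

setValidity("CovariateTable", function(object) {
  d <- object@data
  need <- c("site", "period", covariateNumericCols, "lon", "lat")
  msg <- character()
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  for (cc in covariateNumericCols)
    if (any(!is.finite(d[[cc]]) | d[[cc]] <= 0))
      msg <- c(msg, sprintf("%s must be strictly positive", cc))
  if (anyDuplicated(d[c("site", "period")]))
    msg <- c(msg, "duplicate site/period rows")
  tab <- table(d$site)
  if (length(tab) && any(tab != 2L))
    msg <- c(msg, "every site needs exactly one row per period (2 rows)")
  if (length(msg)) msg else TRUE
})

#' PairedAssemblages: aligned historical and current matrices
#'
#' Both matrices share the identical site order and the union species axis
#' (zero-filled where a species is absent from one period).
#'
#' @slot historical,current AssemblageMatrix on identical dimnames.
#' @slot dropped list with the site/species ids removed during alignment.
#' @exportClass PairedAssemblages
setClass("PairedAssemblages",
  representation(historical = "AssemblageMatrix",
                 current = "AssemblageMatrix",
                 dropped = "list"))

setValidity("PairedAssemblages", function(object) {
  h <- object@historical@occurrence
  c_ <- object@current@occurrence
  if (!identical(dimnames(h), dimnames(c_)))
    return("historical and current must share identical site and species axes")
  TRUE
})

#' FunctionalSpace: species coordinates on PCoA axes
#'
#' Species scores on the first m principal coordinate axes of the functional
#' distance matrix, with the full eigenvalue spectrum and the fraction of
#' positive-eigenvalue variation captured by the retained axes.
#'
#' @slot coordinates species x m numeric matrix, columns PcoA1..PcoAm.
#' @slot eigenvalues full eigenvalue spectrum, descending.
#' @slot quality fraction of positive-eigenvalue mass on the retained axes.
#' @slot metric character, distance metric used.
#' @exportClass FunctionalSpace
setClass("FunctionalSpace",
  representation(coordinates = "matrix", eigenvalues = "numeric",
                 quality = "numeric", metric = "character"))

setValidity("FunctionalSpace", function(object) {
  msg <- character()
  if (is.null(rownames(object@coordinates)))
    msg <- c(msg, "coordinates need species rownames")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (length(object@quality) != 1L || object@quality < 0 ||
      object@quality > 1 + 1e-12)
    msg <- c(msg, "quality must be a single value in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: ground-truth parameters for the data generator
#'
#' Encodes the study design being emulated: number of lakes, regional pool
#' size, occupancy and spatial-turnover structure of the historical matrices,
#' the per-cell loss intensity, trait- and impact-driven components of the
#' extirpation hazard, and the master seed. All generator randomness is fixed
#' by \code{seed}.
#'
#' @slot params named list of generator parameters (see [syntheticScenario()]).
#' @exportClass SyntheticScenario
setClass("SyntheticScenario", representation(params = "list"))

setValidity("SyntheticScenario", function(object) {
  p <- object@params
  msg <- character()
  if (p$n_sites < 2) msg <- c(msg, "need at least 2 sites")
  if (p$pool_size < p$n_sites) msg <- c(msg, "pool_size too small")
  if (p$mean_loss < 0 || p$mean_loss >= 1)
    msg <- c(msg, "mean_loss must be in [0,1)")
  if (length(msg)) msg else TRUE
})
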