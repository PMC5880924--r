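#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("occurrence", "AssemblageMatrix", function(x) x@occurrence)
#' @rdname accessors
setMethod("siteNames", "AssemblageMatrix", function(x) rownames(x@occurrence))
#' @rdname accessors
setMethod("speciesNames", "AssemblageMatrix", function(x) colnames(x@occurrence))
#' @rdname accessors
setMethod("periodLabel", "AssemblageMatrix", function(x) x@period)
#' @rdname accessors
setMethod("emptySites", "AssemblageMatrix",
          function(x) rownames(x@occurrence)[rowSums(x@occurrence) == 0])

#' @rdname accessors
setMethod("siteNames", "PairedAssemblages",
          function(x) rownames(x@historical@occurrence))
#' @rdname accessors
setMethod("speciesNames", "PairedAssemblages",
          function(x) colnames(x@historical@occurrence))
#' @rdname accessors
setMethod("historical", "PairedAssemblages", function(x) x@historical)
#' @rdname accessors
setMethod("current", "PairedAssemblages", function(x) x@current)

#' @rdname accessors
setMethod("traitData", "TraitTable", function(x) x@traits)
#' @rdname accessors
setMethod("vocabulary", "TraitTable", function(x) x@vocabulary)
#' @rdname accessors
setMethod("speciesNames", "TraitTable", function(x) rownames(x@traits))

#' @rdname accessors
setMethod("speciesCoordinates", "FunctionalSpace", function(x) x@coordinates)
#' @rdname accessors
setMethod("eigenvalues", "FunctionalSpace", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("speciesNames", "FunctionalSpace", function(x) rownames(x@coordinates))

#' @rdname accessors
setMethod("covariateData", "CovariateTable", function(x) x@data)
#' @rdname accessors
setMethod("siteNames", "CovariateTable", function(x) unique(x@data$site))

#' @rdname accessors
setMethod("scenarioParams", "SyntheticScenario", function(x) x@params)

setMethod("speciesRichness", "AssemblageMatrix",
          function(x) {
            r <- as.integer(rowSums(x@occurrence))
            names(r) <- rownames(x@occurrence)
            r
          })
setMethod("speciesRichness", "matrix",
          function(x) {
            r <- as.integer(rowSums(x))
            names(r) <- rownames(x)
            r
          })
setMethod("speciesRichness", "numeric", function(x) as.integer(sum(x)))

setMethod("show", "AssemblageMatrix", function(object) {
  occ <- object@occurrence
  cat(sprintf("AssemblageMatrix [%s]: %d sites x %d species, %d presences\n",
              object@period, nrow(occ), ncol(occ), sum(occ)))
  r <- rowSums(occ)
  cat(sprintf("  richness: mean %.1f, range %d-%d; empty sites: %d\n",
              mean(r), min(r), max(r), sum(r == 0)))
})

setMethod("show", "PairedAssemblages", function(object) {
  cat(sprintf("PairedAssemblages: %d sites, %d species (union axis)\n",
              nrow(object@historical@occurrence),
              ncol(object@historical@occurrence)))
  cat(sprintf("  periods: %s -> %s\n", object@historical@period,
              object@current@period))
  if (length(object@dropped))
    cat(sprintf("  dropped during alignment: %d site(s), %d species\n",
                length(object@dropped$sites), length(object@dropped$species)))
})

setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d species, %d traits (%s)\n",
              nrow(object@traits), length(object@vocabulary),
              paste(names(object@vocabulary), collapse = ", ")))
})

setMethod("show", "FunctionalSpace", function(object) {
  cat(sprintf("FunctionalSpace: %d species on %d axes (%s distances)\n",
              nrow(object@coordinates), ncol(object@coordinates),
              object@metric))
  cat(sprintf("  quality: %.3f of positive-eigenvalue variation retained\n",
              object@quality))
})

setMethod("show", "CovariateTable", function(object) {
  d <- object@data
  cat(sprintf("CovariateTable: %d sites x %d periods (%s)\n",
              length(unique(d$site)), length(unique(d$period)),
              paste(unique(d$period), collapse = ", ")))
})

setMethod("show", "SyntheticScenario", function(object) {
  p <- object@params
  cat(sprintf(
    "SyntheticScenario: %d sites, pool %d, mean richness target %.1f\n",
    p$n_sites, p$pool_size, p$mean_richness))
  cat(sprintf("  mean per-cell loss %.2f, turnover strength %.2f, seed %d\n",
              p$mean_loss, p$turnover_strength, p$seed))
})
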