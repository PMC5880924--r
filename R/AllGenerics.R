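#' @include AllClasses.R
NULL

#' Accessors for assemblage and trait containers
#'
#' `occurrence()` returns the binary site x species matrix; `siteNames()` and
#' `speciesNames()` its dimnames; `periodLabel()` the period tag;
#' `historical()`/`current()` the two members of a [PairedAssemblages-class];
#' `traitData()` and `vocabulary()` the contents of a [TraitTable-class];
#' `speciesCoordinates()`, `eigenvalues()` and `spaceQuality()` the contents
#' of a [FunctionalSpace-class]; `covariateData()` the data.frame inside a
#' [CovariateTable-class]; `scenarioParams()` the generator parameter list.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("occurrence", function(x) standardGeneric("occurrence"))
#' @rdname accessors
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("periodLabel", function(x) standardGeneric("periodLabel"))
#' @rdname accessors
#' @export
setGeneric("historical", function(x) standardGeneric("historical"))
#' @rdname accessors
#' @export
setGeneric("current", function(x) standardGeneric("current"))
#' @rdname accessors
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("speciesCoordinates", function(x) standardGeneric("speciesCoordinates"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("covariateData", function(x) standardGeneric("covariateData"))
#' @rdname accessors
#' @export
setGeneric("scenarioParams", function(x) standardGeneric("scenarioParams"))

#' @rdname accessors
#' @export
setGeneric("emptySites", function(x) standardGeneric("emptySites"))

#' Per-site species richness
#'
#' Number of species present at each site (row sums of the binary matrix).
#' For a plain 0/1 vector, the count of 1s.
#'
#' @param x an [AssemblageMatrix-class], binary matrix, or single binary row.
#' @return named integer vector of richness values (a single integer for a
#'   vector input).
#' @export
setGeneric("speciesRichness", function(x) standardGeneric("speciesRichness"))
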