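#' @include AllClasses.R
NULL

#' Default categorical trait vocabulary for lake macrophytes
#'
#' Five traits with the level sets used throughout: life form (submerged,
#' floating_leaved, emergent, free_floating), life cycle (annual, perennial),
#' morphology (turion, stem, rosette, leafy), dispersal range (local,
#' regional, asian_endemic, cosmopolitan) and sexual propagation (monoecism,
#' dioecy) — 16 levels in total.
#'
#' @return named list mapping trait name to its allowed levels.
#' @export
defaultTraitVocabulary <- function() {
  list(
    life_form = c("submerged", "floating_leaved", "emergent", "free_floating"),
    life_cycle = c("annual", "perennial"),
    morphology = c("turion", "stem", "rosette", "leafy"),
    dispersal_range = c("local", "regional", "asian_endemic", "cosmopolitan"),
    sexual_propagation = c("monoecism", "dioecy")
  )
}

#' Construct an AssemblageMatrix from a binary matrix
#'
#' @param occurrence numeric 0/1 matrix with site rownames and species
#'   colnames.
#' @param period period label.
#' @return validated [AssemblageMatrix-class].
#' @export
assemblageMatrix <- function(occurrence, period = "unspecified") {
  storage.mode(occurrence) <- "double"
  new("AssemblageMatrix", occurrence = occurrence, period = period)
}

#' Read a site-by-species presence/absence matrix
#'
#' Wide format: first column the site id, remaining columns one per species,
#' cells 0/1. Long format: columns `site` and `species` (one row per
#' occurrence record); duplicate records collapse to a single presence (OR
#' semantics, mirroring the pooling of repeat surveys).
#'
#' @param source path to a delimited text file.
#' @param dialect `"wide"` (canonical) or `"long"`.
#' @param period period label attached to the result.
#' @param sep field separator (default `,`).
#' @return an [AssemblageMatrix-class].
#' @export
readAssemblageMatrix <- function(source, dialect = c("wide", "long"),
                                 period = "unspecified", sep = ",") {
  dialect <- match.arg(dialect)
  d <- utils::read.table(source, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    sites <- as.character(d[[1L]])
    if (anyDuplicated(sites))
      stop("duplicate site id in wide matrix: ",
           paste(unique(sites[duplicated(sites)]), collapse = ", "),
           call. = FALSE)
    occ <- as.matrix(d[, -1L, drop = FALSE])
    if (!is.numeric(occ))
      stop("wide matrix cells must be numeric 0/1", call. = FALSE)
    stopIfNot01(occ, "wide occurrence matrix")
    rownames(occ) <- sites
  } else {
    need <- c("site", "species")
    if (!all(need %in% names(d)))
      stop("long format needs columns 'site' and 'species'", call. = FALSE)
    sites <- unique(as.character(d$site))
    spp <- unique(as.character(d$species))
    occ <- matrix(0, length(sites), length(spp),
                  dimnames = list(sites, spp))
    occ[cbind(as.character(d$site), as.character(d$species))] <- 1
  }
  assemblageMatrix(occ, period = period)
}

#' Write an AssemblageMatrix as wide CSV
#'
#' Inverse of [readAssemblageMatrix()] for the wide dialect; round-trips
#' bit-exactly.
#'
#' @param x an [AssemblageMatrix-class].
#' @param path output file path.
#' @export
writeAssemblageMatrix <- function(x, path) {
  occ <- occurrence(x)
  d <- data.frame(site = rownames(occ), occ, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a species trait table
#'
#' One row per species; a `species` column plus one column per trait in the
#' vocabulary. Level spelling is normalized case-insensitively (and spaces
#' and hyphens map to underscores) before validation. An optional logical
#' `invasive` column marks species excluded from analysis when
#' `dropInvasive = TRUE`.
#'
#' @param source path to a delimited text file.
#' @param vocab trait vocabulary (named list); default
#'   [defaultTraitVocabulary()].
#' @param dropInvasive drop rows flagged in an `invasive` column
#'   (default FALSE).
#' @param sep field separator.
#' @return a [TraitTable-class].
#' @export
readTraitTable <- function(source, vocab = defaultTraitVocabulary(),
                           dropInvasive = FALSE, sep = ",") {
  d <- utils::read.table(source, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!"species" %in% names(d))
    stop("trait table needs a 'species' column", call. = FALSE)
  if (dropInvasive && "invasive" %in% names(d))
    d <- d[!as.logical(d$invasive), , drop = FALSE]
  traitTable(d[setdiff(names(d), "invasive")], vocab = vocab)
}

#' Construct a TraitTable from a data.frame
#'
#' @param d data.frame with a `species` column (or species rownames) and one
#'   column per trait.
#' @param vocab trait vocabulary.
#' @return a validated [TraitTable-class].
#' @export
traitTable <- function(d, vocab = defaultTraitVocabulary()) {
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  if ("species" %in% names(d)) {
    if (anyDuplicated(d$species))
      stop("duplicate species id in trait table", call. = FALSE)
    rownames(d) <- d$species
    d$species <- NULL
  }
  miss <- setdiff(names(vocab), names(d))
  if (length(miss))
    stop("trait table missing trait(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- d[names(vocab)]
  norm <- function(v) gsub("[ -]", "_", tolower(trimws(as.character(v))))
  for (nm in names(vocab)) {
    v <- norm(d[[nm]])
    if (any(v == "" | is.na(v)))
      stop(sprintf("missing %s value(s)", nm), call. = FALSE)
    bad <- setdiff(unique(v), vocab[[nm]])
    if (length(bad))
      stop(sprintf("unknown level(s) for trait %s: %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
    d[[nm]] <- factor(v, levels = vocab[[nm]])
  }
  new("TraitTable", traits = d, vocabulary = vocab)
}

#' Write a TraitTable as CSV
#' @param x a [TraitTable-class].
#' @param path output path.
#' @export
writeTraitTable <- function(x, path) {
  d <- data.frame(species = rownames(traitData(x)),
                  lapply(traitData(x), as.character),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-site covariate table
#'
#' Columns: site, period, area_km2, tp_mg_l, secchi_cm, catch_t_km2, lon,
#' lat. Every retained site needs one row per period and strictly positive
#' physical quantities.
#'
#' @param source path to a delimited file.
#' @param sep field separator.
#' @return a [CovariateTable-class].
#' @export
readCovariateTable <- function(source, sep = ",") {
  d <- utils::read.table(source, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  covariateTable(d)
}

#' Construct a CovariateTable from a data.frame
#' @param d data.frame; see [readCovariateTable()] for the columns.
#' @return a validated [CovariateTable-class].
#' @export
covariateTable <- function(d) {
  d$site <- as.character(d$site)
  d$period <- as.character(d$period)
  new("CovariateTable", data = as.data.frame(d))
}

#' Write a CovariateTable as CSV
#' @param x a [CovariateTable-class].
#' @param path output path.
#' @export
writeCovariateTable <- function(x, path) {
  utils::write.csv(covariateData(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align the two survey periods onto shared sites and the union species axis
#'
#' Sites are intersected (keeping the historical order); the species axis
#' becomes the union of both periods' species, zero-filled where absent.
#' Species absent from both periods are dropped silently. Sites present in
#' only one period are dropped and reported; sites that are empty in one
#' period but surveyed in both are retained (richness 0) and flagged via
#' [emptySites()].
#'
#' @param hist,curr validated [AssemblageMatrix-class] objects.
#' @return a [PairedAssemblages-class]; its `dropped` slot lists removed
#'   sites/species.
#' @export
alignPeriods <- function(hist, curr) {
  sh <- siteNames(hist); sc <- siteNames(curr)
  sites <- sh[sh %in% sc]
  if (!length(sites))
    stop("no site shared between the two periods", call. = FALSE)
  droppedSites <- c(setdiff(sh, sites), setdiff(sc, sites))
  spp <- union(speciesNames(hist), speciesNames(curr))
  fill <- function(occ) {
    m <- matrix(0, length(sites), length(spp), dimnames = list(sites, spp))
    keep <- intersect(colnames(occ), spp)
    m[, keep] <- occ[sites, keep, drop = FALSE]
    m
  }
  h <- fill(occurrence(hist)); c_ <- fill(occurrence(curr))
  keepSpp <- colSums(h) + colSums(c_) > 0
  droppedSpecies <- spp[!keepSpp]
  h <- h[, keepSpp, drop = FALSE]; c_ <- c_[, keepSpp, drop = FALSE]
  if (length(droppedSites))
    warning("dropped site(s) absent from one period: ",
            paste(droppedSites, collapse = ", "), call. = FALSE)
  new("PairedAssemblages",
      historical = assemblageMatrix(h, periodLabel(hist)),
      current = assemblageMatrix(c_, periodLabel(curr)),
      dropped = list(sites = droppedSites, species = droppedSpecies))
}

#' Report species lacking trait coverage
#'
#' Species on the paired species axis that are absent from the trait table.
#'
#' @param paired a [PairedAssemblages-class].
#' @param traits a [TraitTable-class].
#' @return character vector of traitless species ids (possibly empty).
#' @export
traitlessSpecies <- function(paired, traits) {
  setdiff(speciesNames(paired), speciesNames(traits))
}
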