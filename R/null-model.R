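#' @include diversity.R utils.R
NULL

#' Simulate a current assemblage matrix under random regional species loss
#'
#' Removes ceiling(lossFraction * S) species from the historical regional
#' pool (S = species with at least one historical presence), either uniformly
#' at random or with removal probability inversely proportional to historical
#' occupancy (`"occupancy_weighted"`, so widespread species are less likely
#' to be lost). Each site's simulated current assemblage is then a uniform
#' subsample of its surviving historical species, of size equal to the
#' observed current richness capped at the survivors available — current row
#' sums are preserved up to that cap.
#'
#' @param paired a [PairedAssemblages-class].
#' @param lossFraction fraction of the historical pool removed, in \[0, 1).
#' @param scheme `"uniform"` (default) or `"occupancy_weighted"`.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @return an [AssemblageMatrix-class] with period "null"; attribute
#'   `capped_sites` counts sites whose target richness exceeded availability.
#' @export
randomizeCurrent <- function(paired, lossFraction,
                             scheme = c("uniform", "occupancy_weighted"),
                             seed = NULL) {
  scheme <- match.arg(scheme)
  if (lossFraction < 0 || lossFraction >= 1)
    stop("lossFraction must be in [0, 1)", call. = FALSE)
  occH <- occurrence(historical(paired))
  occC <- occurrence(current(paired))
  occupancy <- colSums(occH)
  pool <- which(occupancy > 0)
  nRemove <- ceiling(lossFraction * length(pool))
  withSeed(seed, {
    removed <- if (nRemove == 0) integer(0)
    else if (scheme == "uniform") sample(pool, nRemove)
    else sample(pool, nRemove, prob = 1 / occupancy[pool])
    sim <- matrix(0, nrow(occH), ncol(occH), dimnames = dimnames(occH))
    targets <- rowSums(occC)
    capped <- 0L
    for (i in seq_len(nrow(occH))) {
      avail <- setdiff(which(occH[i, ] > 0), removed)
      k <- min(targets[i], length(avail))
      if (k < targets[i]) capped <- capped + 1L
      if (k > 0) sim[i, sample(avail, k)] <- 1
    }
    structure(assemblageMatrix(sim, period = "null"), capped_sites = capped)
  })
}

#' Monte Carlo null-model test of the mean pairwise nestedness component
#'
#' Compares the observed mean pairwise nestedness component of the current
#' assemblages against a null distribution obtained by repeatedly simulating
#' current assemblages under random regional species loss (see
#' [randomizeCurrent()]). The default loss fraction is the observed pool
#' reduction. The p-value is for the "observed greater" alternative:
#' p = (#\{null >= observed\} + 1) / (nreps + 1).
#'
#' @param paired a [PairedAssemblages-class].
#' @param nreps number of Monte Carlo replicates (default 9999).
#' @param seed integer seed fixing the whole simulation.
#' @param lossFraction fraction of the historical pool removed per replicate;
#'   default the observed pool reduction.
#' @param scheme randomization scheme, see [randomizeCurrent()].
#' @param family dissimilarity family for the partition.
#' @return list with `observed`, `null_mean`, `null_sd`, `p`, `nreps`,
#'   `loss_fraction`, `scheme`, `seed`, `null` (the replicate statistics).
#' @export
nullNestednessTest <- function(paired, nreps = 9999L, seed = NULL,
                               lossFraction = NULL,
                               scheme = c("uniform", "occupancy_weighted"),
                               family = c("jaccard", "sorensen")) {
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  if (nreps < 1) stop("nreps must be >= 1", call. = FALSE)
  occH <- occurrence(historical(paired))
  occC <- occurrence(current(paired))
  if (all(rowSums(occC) == 0)) stop("all current assemblages empty", call. = FALSE)
  if (is.null(lossFraction)) {
    sHist <- sum(colSums(occH) > 0)
    sCurr <- sum(colSums(occC) > 0)
    lossFraction <- max(0, (sHist - sCurr) / sHist)
  }
  observed <- meanPairwiseNestedness(occC, family)
  null <- withSeed(seed, vapply(seq_len(nreps), function(k) {
    sim <- randomizeCurrent(paired, lossFraction, scheme, seed = NULL)
    meanPairwiseNestedness(occurrence(sim), family)
  }, numeric(1)))
  list(observed = observed, null_mean = mean(null), null_sd = stats::sd(null),
       p = (sum(null >= observed) + 1) / (nreps + 1),
       nreps = nreps, loss_fraction = lossFraction, scheme = scheme,
       seed = seed, null = null)
}
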