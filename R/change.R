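#' @include diversity.R
NULL

#' Signed temporal change of a diversity index
#'
#' Current minus historical; positive values indicate an increase between
#' periods. NA in either period propagates.
#'
#' @param hist,curr index values (vectors recycle as usual).
#' @return curr - hist.
#' @export
changeIndex <- function(hist, curr) curr - hist

#' Percent reduction of the regional species pool
#'
#' @param histPool,currPool species counts of the regional pool in the two
#'   periods.
#' @return 100 * (histPool - currPool) / histPool.
#' @export
poolReduction <- function(histPool, currPool) {
  if (histPool <= 0) stop("historical pool size must be positive", call. = FALSE)
  100 * (histPool - currPool) / histPool
}

indexNames <- c("richness_ratio_tax", "tax_total",
                "tax_turnover_contribution", "tax_nestedness_contribution",
                "richness_ratio_fun", "fun_total",
                "fun_turnover_contribution", "fun_nestedness_contribution")

#' Per-pair and per-site temporal changes of the eight diversity indices
#'
#' Computes the pairwise beta table for each period and the change
#' (current - historical) of the eight indices per site pair: richness ratio,
#' total dissimilarity, turnover contribution and nestedness contribution,
#' each for the taxonomic and (if a space is given) functional facet. Pairs
#' are classified as homogenization (change in total dissimilarity <= 0,
#' zeros binned with homogenization) or differentiation (> 0) per facet, and
#' functional classes are cross-labeled by the taxonomic class (TH/TD).
#' Per-site changes in species richness and functional richness are returned
#' alongside.
#'
#' @param paired a [PairedAssemblages-class].
#' @param space optional [FunctionalSpace-class]; enables the functional
#'   facet. FRic is standardized by the combined two-period pool hull.
#' @param family `"jaccard"` (default) or `"sorensen"`.
#' @param pairLoss how to count species loss within a pair for downstream
#'   Mantel tests: `"union"` (species lost from the union of the two
#'   historical assemblages, default) or `"sum"` (sum of per-site losses).
#' @return list with `pairs` (per-pair hist/curr/change columns, classes) and
#'   `sites` (per-site richness and FRic changes).
#' @export
temporalChanges <- function(paired, space = NULL,
                            family = c("jaccard", "sorensen"),
                            pairLoss = c("union", "sum")) {
  family <- match.arg(family)
  pairLoss <- match.arg(pairLoss)
  h <- historical(paired); cu <- current(paired)
  bh <- pairwiseBeta(h, space, family)
  bc <- pairwiseBeta(cu, space, family)
  pairs <- bh[c("site_i", "site_j")]
  for (nm in intersect(indexNames, names(bh))) {
    pairs[[paste0(nm, "_hist")]] <- bh[[nm]]
    pairs[[paste0(nm, "_curr")]] <- bc[[nm]]
    pairs[[paste0(nm, "_change")]] <- changeIndex(bh[[nm]], bc[[nm]])
  }
  pairs$tax_class <- ifelse(pairs$tax_total_change > 0,
                            "differentiation", "homogenization")
  if (!is.null(space)) {
    pairs$fun_class <- ifelse(pairs$fun_total_change > 0,
                              "differentiation", "homogenization")
    pairs$cross_class <- ifelse(pairs$tax_class == "homogenization",
                                "TH", "TD")
    pairs$fun_degenerate <- bh$fun_degenerate | bc$fun_degenerate
  }
  pairs$pair_species_loss <- pairwiseSpeciesLoss(paired, pairLoss)

  occH <- occurrence(h); occC <- occurrence(cu)
  rh <- rowSums(occH); rc <- rowSums(occC)
  sites <- data.frame(site = rownames(occH),
                      richness_hist = rh, richness_curr = rc,
                      richness_change = rc - rh,
                      richness_pct_change = ifelse(rh > 0,
                                                   100 * (rc - rh) / rh,
                                                   NA_real_),
                      row.names = NULL)
  if (!is.null(space)) {
    co <- speciesCoordinates(space)
    poolVol <- as.numeric(hullVolume(co))
    fr <- function(occ) vapply(seq_len(nrow(occ)), function(i) {
      m <- colnames(occ)[occ[i, ] > 0]
      as.numeric(hullVolume(co[m, , drop = FALSE])) / poolVol
    }, numeric(1))
    sites$fric_hist <- fr(occH)
    sites$fric_curr <- fr(occC)
    sites$fric_change <- sites$fric_curr - sites$fric_hist
  }
  structure(list(pairs = pairs, sites = sites), family = family)
}

#' Species lost within each site pair
#'
#' `"union"` counts species lost from the union of the two historical
#' assemblages (present historically at either site, currently at neither);
#' `"sum"` adds the two per-site local losses. Pairs are in the same order as
#' the [pairwiseBeta()] table.
#'
#' @param paired a [PairedAssemblages-class].
#' @param method `"union"` (default) or `"sum"`.
#' @return numeric vector, one value per unordered site pair.
#' @export
pairwiseSpeciesLoss <- function(paired, method = c("union", "sum")) {
  method <- match.arg(method)
  occH <- occurrence(historical(paired))
  occC <- occurrence(current(paired))
  n <- nrow(occH)
  idx <- pairIndex(n)
  if (method == "union") {
    lost <- (occH == 1) & (occC == 0)  # per site-species local loss
    # species lost from the union: present historically at i or j, and not
    # present currently at either
    vapply(seq_len(nrow(idx)), function(k) {
      i <- idx$i[k]; j <- idx$j[k]
      histU <- occH[i, ] > 0 | occH[j, ] > 0
      currU <- occC[i, ] > 0 | occC[j, ] > 0
      sum(histU & !currU)
    }, numeric(1))
  } else {
    lossPerSite <- rowSums((occH == 1) & (occC == 0))
    lossPerSite[idx$i] + lossPerSite[idx$j]
  }
}

#' Classify and summarize temporal changes (frequency and intensity)
#'
#' Tabulates, per facet, the percentage of site pairs falling in each
#' change class and the mean +/- SD of the corresponding deltas: total
#' dissimilarity change split into homogenization (<= 0, zeros binned here)
#' vs differentiation (> 0), and strict decreases/increases of the turnover
#' and nestedness contributions. Functional cells are additionally split by
#' the taxonomic class of the same pair (TH/TD). Percentages are relative to
#' the pairs with a defined (non-NA) delta for the facet.
#'
#' @param changes output of [temporalChanges()].
#' @return data.frame with columns facet, measure, direction, cross, n,
#'   percent, mean, sd; attribute `n_zero` counts exact-zero deltas per
#'   facet/measure.
#' @export
classifyChanges <- function(changes) {
  pairs <- changes$pairs
  if (!nrow(pairs)) stop("empty change table", call. = FALSE)
  hasFun <- "fun_total_change" %in% names(pairs)
  rows <- list()
  zeros <- list()
  cell <- function(delta, sel, facet, measure, direction, cross, nTot) {
    v <- delta[sel]
    data.frame(facet = facet, measure = measure, direction = direction,
               cross = cross, n = length(v),
               percent = 100 * length(v) / nTot,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  facets <- if (hasFun) c("taxonomic", "functional") else "taxonomic"
  for (facet in facets) {
    px <- if (facet == "taxonomic") "tax_" else "fun_"
    dTot <- pairs[[paste0(px, "total_change")]]
    ok <- !is.na(dTot)
    nTot <- sum(ok)
    specs <- list(
      list(measure = "total", delta = dTot,
           dir = list(homogenization = !is.na(dTot) & dTot <= 0,
                      differentiation = !is.na(dTot) & dTot > 0)),
      list(measure = "turnover_contribution",
           delta = pairs[[paste0(px, "turnover_contribution_change")]],
           dir = NULL),
      list(measure = "nestedness_contribution",
           delta = pairs[[paste0(px, "nestedness_contribution_change")]],
           dir = NULL))
    for (sp in specs) {
      d <- sp$delta
      dirs <- if (is.null(sp$dir))
        list(decrease = !is.na(d) & d < 0, increase = !is.na(d) & d > 0)
      else lapply(sp$dir, function(s) s & ok)
      zeros[[paste(facet, sp$measure)]] <- sum(!is.na(d) & d == 0)
      for (dn in names(dirs)) {
        sel <- dirs[[dn]] & ok
        rows[[length(rows) + 1L]] <-
          cell(d, sel, facet, sp$measure, dn, NA_character_, nTot)
        if (facet == "functional") {
          for (cl in c("TH", "TD")) {
            selc <- sel & pairs$cross_class == cl
            rows[[length(rows) + 1L]] <-
              cell(d, selc, facet, sp$measure, dn, cl, nTot)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_zero") <- unlist(zeros)
  out
}

#' Per-species extirpation and colonization counts
#'
#' For every species on the paired axis: historical occupancy, current
#' occupancy, loss (sites occupied historically but not currently) and
#' colonization (the converse), counted separately, never netted.
#'
#' @param paired a [PairedAssemblages-class].
#' @return data.frame with one row per species.
#' @export
extirpationCounts <- function(paired) {
  occH <- occurrence(historical(paired))
  occC <- occurrence(current(paired))
  data.frame(
    species = colnames(occH),
    occupancy_hist = colSums(occH),
    occupancy_curr = colSums(occC),
    loss = colSums(occH == 1 & occC == 0),
    colonization = colSums(occH == 0 & occC == 1),
    row.names = NULL)
}

#' Table-1-style summary of diversity levels and changes
#'
#' Mean +/- SD and range of each pairwise index (richness ratio, total
#' dissimilarity, turnover and nestedness contributions; both facets) for the
#' historical period, the current period, and their change.
#'
#' @param changes output of [temporalChanges()].
#' @return data.frame with columns index, facet, period, mean, sd, min, max, n.
#' @export
diversitySummary <- function(changes) {
  pairs <- changes$pairs
  present <- indexNames[vapply(indexNames, function(nm)
    paste0(nm, "_hist") %in% names(pairs), logical(1))]
  rows <- lapply(present, function(nm) {
    facet <- if (grepl("fun", nm)) "functional" else "taxonomic"
    index <- sub("_(tax|fun)$", "", sub("^(tax|fun)_", "", nm))
    # restrict to pairs measurable in both periods so that
    # mean(change) = mean(current) - mean(historical) holds row by row
    keep <- !is.na(pairs[[paste0(nm, "_change")]])
    do.call(rbind, lapply(c("hist", "curr", "change"), function(p) {
      v <- pairs[[paste0(nm, "_", p)]][keep]
      data.frame(index = index, facet = facet,
                 period = c(hist = "historical", curr = "current",
                            change = "change")[[p]],
                 mean = mean(v), sd = stats::sd(v),
                 min = min(v), max = max(v), n = length(v))
    }))
  })
  do.call(rbind, rows)
}

#' Mean richness decline between periods
#'
#' Two distinct statistics: the decline of the mean per-site richness
#' (100 * (mean_hist - mean_curr) / mean_hist) and the mean of the per-site
#' percentage declines, plus a paired t-test of per-site richness.
#'
#' @param paired a [PairedAssemblages-class].
#' @return list with `decline_of_means_pct`, `mean_of_site_declines_pct`,
#'   `mean_hist`, `mean_curr`, `sd_hist`, `sd_curr`, `t`, `df`, `p`.
#' @export
richnessDecline <- function(paired) {
  rh <- rowSums(occurrence(historical(paired)))
  rc <- rowSums(occurrence(current(paired)))
  tt <- pairedTTest(rh, rc)
  list(decline_of_means_pct = 100 * (mean(rh) - mean(rc)) / mean(rh),
       mean_of_site_declines_pct = mean(100 * (rh - rc) / rh),
       mean_hist = mean(rh), mean_curr = mean(rc),
       sd_hist = stats::sd(rh), sd_curr = stats::sd(rc),
       t = tt$t, df = tt$df, p = tt$p)
}
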