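#' @include AllClasses.R geometry.R
NULL

#' Standardized functional richness (FRic) of one assemblage
#'
#' Convex-hull volume of the assemblage's species in functional space,
#' divided by the hull volume of the species pool, so values range from 0
#' (single species, or any hull-degenerate assemblage) to 1 (assemblage
#' filling the pool's hull).
#'
#' @param members character vector of species present (or a named binary row).
#' @param space a [FunctionalSpace-class] covering all members.
#' @param poolVolume hull volume of the pool; default the hull volume of all
#'   species in `space`.
#' @return FRic in \[0, 1\]; degenerate hulls give 0.
#' @export
functionalRichness <- function(members, space, poolVolume = NULL) {
  co <- speciesCoordinates(space)
  if (is.numeric(members) && !is.null(names(members)))
    members <- names(members)[members > 0]
  miss <- setdiff(members, rownames(co))
  if (length(miss))
    stop("species missing functional coordinates: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  if (is.null(poolVolume)) poolVolume <- as.numeric(hullVolume(co))
  if (poolVolume <= 0) stop("pool hull volume must be positive", call. = FALSE)
  v <- hullVolume(co[members, , drop = FALSE])
  as.numeric(v) / poolVolume
}

#' Shared/unique components of a pair of assemblages
#'
#' `taxonomicComponents()` counts species: a = shared, b = unique to the
#' first row, c = unique to the second. `functionalComponents()` measures
#' convex-hull volumes in functional space: a = volume of the hull
#' intersection, b and c the volumes unique to each hull. Pairs where either
#' hull is degenerate (fewer than d+1 affinely independent species) are not
#' measurable and return NA components.
#'
#' @param x,y binary occurrence rows on the same species axis (named, or
#'   plain vectors of equal length).
#' @return list with `a`, `b`, `c` and `mode` (`"counts"` or `"volumes"`).
#' @export
taxonomicComponents <- function(x, y) {
  if (length(x) != length(y))
    stop("rows must share the species axis", call. = FALSE)
  a <- sum(x == 1 & y == 1)
  list(a = a, b = sum(x == 1 & y == 0), c = sum(x == 0 & y == 1),
       mode = "counts")
}

#' @rdname taxonomicComponents
#' @param space a [FunctionalSpace-class] (functional variant only).
#' @export
functionalComponents <- function(x, y, space) {
  co <- speciesCoordinates(space)
  mx <- names(x)[x > 0]; my <- names(y)[y > 0]
  if (is.null(mx) || is.null(my))
    stop("rows must be named by species", call. = FALSE)
  vx <- hullVolume(co[mx, , drop = FALSE])
  vy <- hullVolume(co[my, , drop = FALSE])
  if (attr(vx, "degenerate") || attr(vy, "degenerate"))
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, mode = "volumes"))
  a <- intersectionVolume(co[mx, , drop = FALSE], co[my, , drop = FALSE])
  list(a = a, b = as.numeric(vx) - a, c = as.numeric(vy) - a,
       mode = "volumes")
}

#' Partition pairwise dissimilarity into turnover and nestedness
#'
#' Jaccard family (default): total D = (b+c)/(a+b+c); turnover
#' D_tu = 2 min(b,c) / (a + 2 min(b,c)); nestedness D_ne = D - D_tu.
#' Sorensen family: D = (b+c)/(2a+b+c); D_tu = min(b,c)/(a+min(b,c)).
#' The same formulas apply to species counts and to hull volumes.
#'
#' @param a shared magnitude; @param b,c magnitudes unique to each
#'   assemblage (counts or volumes).
#' @param family `"jaccard"` (default) or `"sorensen"`.
#' @return list with `total`, `turnover`, `nestedness`,
#'   `turnover_contribution`, `nestedness_contribution` (contributions NA
#'   when total = 0).
#' @export
betaPartition <- function(a, b, c, family = c("jaccard", "sorensen")) {
  family <- match.arg(family)
  if (anyNA(c(a, b, c)))
    return(list(total = NA_real_, turnover = NA_real_, nestedness = NA_real_,
                turnover_contribution = NA_real_,
                nestedness_contribution = NA_real_))
  if (any(c(a, b, c) < 0)) stop("components must be nonnegative", call. = FALSE)
  if (a + b + c == 0) stop("empty pair: a + b + c = 0", call. = FALSE)
  mn <- pmin(b, c)
  if (family == "jaccard") {
    total <- (b + c) / (a + b + c)
    turnover <- if (mn == 0) 0 else 2 * mn / (a + 2 * mn)
  } else {
    total <- (b + c) / (2 * a + b + c)
    turnover <- if (mn == 0) 0 else mn / (a + mn)
  }
  nest <- total - turnover
  list(total = total, turnover = turnover, nestedness = nest,
       turnover_contribution = if (total > 0) turnover / total else NA_real_,
       nestedness_contribution = if (total > 0) nest / total else NA_real_)
}

#' Pairwise beta-diversity table for one period
#'
#' One record per unordered site pair: taxonomic partition (always),
#' functional partition (when a functional space is supplied), richness
#' ratios (min/max within the pair, taxonomic and, if available, functional),
#' and hull-degeneracy flags. Volumes below 1e-12 of the pool volume are
#' clamped to 0 to stabilize ratios.
#'
#' @param x an [AssemblageMatrix-class].
#' @param space optional [FunctionalSpace-class] covering all species in `x`.
#' @param family dissimilarity family, `"jaccard"` or `"sorensen"`.
#' @param poolVolume pool hull volume for FRic standardization; default the
#'   hull of all species in `space`.
#' @return data.frame with n(n-1)/2 rows and columns site_i, site_j,
#'   richness ratios, and per-facet total/turnover/nestedness and
#'   contributions (functional columns NA where a hull is degenerate).
#' @export
pairwiseBeta <- function(x, space = NULL, family = c("jaccard", "sorensen"),
                         poolVolume = NULL) {
  family <- match.arg(family)
  occ <- occurrence(x)
  n <- nrow(occ)
  if (n < 2L) stop("need at least two sites", call. = FALSE)
  idx <- pairIndex(n)
  shared <- occ %*% t(occ)
  rich <- rowSums(occ)
  a <- shared[cbind(idx$j, idx$i)]
  b <- rich[idx$i] - a
  cc <- rich[idx$j] - a
  tax <- betaPartitionVec(a, b, cc, family)
  res <- data.frame(
    site_i = rownames(occ)[idx$i], site_j = rownames(occ)[idx$j],
    richness_i = rich[idx$i], richness_j = rich[idx$j],
    richness_ratio_tax = pmin(rich[idx$i], rich[idx$j]) /
      pmax(rich[idx$i], rich[idx$j]),
    tax_a = a, tax_b = b, tax_c = cc,
    tax_total = tax$total, tax_turnover = tax$turnover,
    tax_nestedness = tax$nestedness,
    tax_turnover_contribution = tax$turnover_contribution,
    tax_nestedness_contribution = tax$nestedness_contribution,
    row.names = NULL)

  if (!is.null(space)) {
    co <- speciesCoordinates(space)
    miss <- setdiff(colnames(occ), rownames(co))
    if (length(miss))
      stop("functional space lacks coordinates for: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    if (is.null(poolVolume)) poolVolume <- as.numeric(hullVolume(co))
    eps <- 1e-12 * poolVolume
    hulls <- lapply(seq_len(n), function(i) {
      convexHull(co[colnames(occ)[occ[i, ] > 0], , drop = FALSE])
    })
    vols <- vapply(hulls, function(h) if (h$degenerate) 0 else h$volume,
                   numeric(1))
    scale <- cloudScale(co)
    m <- nrow(idx)
    fa <- fb <- fc <- rep(NA_real_, m)
    for (k in seq_len(m)) {
      hi <- hulls[[idx$i[k]]]; hj <- hulls[[idx$j[k]]]
      if (hi$degenerate || hj$degenerate) next
      ov <- hullIntersectionVolume(hi, hj, 1e-9 * scale)
      if (ov < eps) ov <- 0
      fa[k] <- ov
      fb[k] <- max(vols[idx$i[k]] - ov, 0)
      fc[k] <- max(vols[idx$j[k]] - ov, 0)
    }
    fun <- betaPartitionVec(fa, fb, fc, family)
    fric <- vols / poolVolume
    res$fric_i <- fric[idx$i]
    res$fric_j <- fric[idx$j]
    res$richness_ratio_fun <- ifelse(
      pmax(fric[idx$i], fric[idx$j]) > 0,
      pmin(fric[idx$i], fric[idx$j]) / pmax(fric[idx$i], fric[idx$j]),
      NA_real_)
    res$fun_a <- fa; res$fun_b <- fb; res$fun_c <- fc
    res$fun_total <- fun$total
    res$fun_turnover <- fun$turnover
    res$fun_nestedness <- fun$nestedness
    res$fun_turnover_contribution <- fun$turnover_contribution
    res$fun_nestedness_contribution <- fun$nestedness_contribution
    res$fun_degenerate <- is.na(fa)
  }
  attr(res, "family") <- family
  res
}

# vectorized partition over component vectors; NAs propagate and pairs with
# an empty union (a + b + c = 0, both assemblages empty) come back NA
betaPartitionVec <- function(a, b, c, family) {
  tot <- a + b + c
  empty <- !is.na(tot) & tot == 0
  a[empty] <- NA_real_; b[empty] <- NA_real_; c[empty] <- NA_real_
  mn <- pmin(b, c)
  if (family == "jaccard") {
    total <- (b + c) / tot
    turnover <- ifelse(mn > 0, 2 * mn / (a + 2 * mn), 0)
  } else {
    total <- (b + c) / (2 * a + b + c)
    turnover <- ifelse(mn > 0, mn / (a + mn), 0)
  }
  turnover[is.na(total)] <- NA_real_
  nest <- total - turnover
  list(total = total, turnover = turnover, nestedness = nest,
       turnover_contribution = ifelse(total > 0, turnover / total, NA_real_),
       nestedness_contribution = ifelse(total > 0, nest / total, NA_real_))
}

# mean pairwise taxonomic nestedness component of a binary matrix;
# the null-model statistic. Pairs with an empty union are dropped.
meanPairwiseNestedness <- function(occ, family = "jaccard") {
  n <- nrow(occ)
  idx <- pairIndex(n)
  shared <- occ %*% t(occ)
  rich <- rowSums(occ)
  a <- shared[cbind(idx$j, idx$i)]
  b <- rich[idx$i] - a
  c_ <- rich[idx$j] - a
  tot <- a + b + c_
  keep <- tot > 0
  a <- a[keep]; b <- b[keep]; c_ <- c_[keep]
  mn <- pmin(b, c_)
  if (family == "jaccard") {
    total <- (b + c_) / (a + b + c_)
    turnover <- ifelse(mn > 0, 2 * mn / (a + 2 * mn), 0)
  } else {
    total <- (b + c_) / (2 * a + b + c_)
    turnover <- ifelse(mn > 0, mn / (a + mn), 0)
  }
  mean(total - turnover)
}
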