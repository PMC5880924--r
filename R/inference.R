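#' @include utils.R
NULL

#' Transform and min-max standardize a predictor
#'
#' Applies the requested transform, then rescales to \[0, 1\]. Used for the
#' human-impact covariates before regression (defaults in the pipeline:
#' area and TP log-transformed, Secchi square-rooted).
#'
#' @param values numeric vector.
#' @param transform `"none"`, `"log"` or `"sqrt"`.
#' @return values in \[0, 1\].
#' @export
transformStandardize <- function(values, transform = c("none", "log", "sqrt")) {
  transform <- match.arg(transform)
  if (transform == "log") {
    if (any(values <= 0)) stop("log transform requires positive values",
                               call. = FALSE)
    values <- log(values)
  } else if (transform == "sqrt") {
    if (any(values < 0)) stop("sqrt transform requires nonnegative values",
                              call. = FALSE)
    values <- sqrt(values)
  }
  r <- range(values)
  if (diff(r) == 0) stop("constant vector cannot be standardized", call. = FALSE)
  (values - r[1]) / diff(r)
}

#' Relative change between periods
#'
#' @param hist,curr values in the two periods (vectors recycle).
#' @return (curr - hist) / hist.
#' @export
relativeChange <- function(hist, curr) {
  if (any(hist == 0)) stop("relative change undefined for zero baseline",
                           call. = FALSE)
  (curr - hist) / hist
}

# all permutations of 1..n (n <= 8), one per column
allPermutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(rec(v[-i]), function(r) c(v[i], r)))
    out
  }
  do.call(cbind, rec(seq_len(n)))
}

checkSquareSymmetric <- function(m, name) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop(name, " must be a square symmetric matrix", call. = FALSE)
  m
}

#' Mantel permutation test between two distance/proximity matrices
#'
#' Correlation (Pearson or Spearman) between the lower triangles, with
#' significance from simultaneous row/column permutations of the second
#' matrix. The default p-value is two-sided on |r| with the +1 correction:
#' p = (#\{|r*| >= |r|\} + 1) / (nperm + 1). With `exact = TRUE` all n!
#' relabelings are enumerated (n <= 8) and p is the exact proportion
#' (identity included).
#'
#' @param A,B square symmetric matrices with matching site order.
#' @param method `"pearson"` or `"spearman"`.
#' @param nperm number of random permutations (default 10000).
#' @param seed optional integer for reproducible permutations.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact enumerate all permutations instead of sampling.
#' @return list with `r`, `p`, `nperm`, `method`, `alternative`, `seed`.
#' @export
mantelTest <- function(A, B, method = c("pearson", "spearman"),
                       nperm = 10000L, seed = NULL,
                       alternative = c("two.sided", "greater", "less"),
                       exact = FALSE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  A <- checkSquareSymmetric(A, "A"); B <- checkSquareSymmetric(B, "B")
  if (!identical(dim(A), dim(B)))
    stop("A and B must have the same dimension", call. = FALSE)
  n <- nrow(A)
  lt <- lower.tri(A)
  a <- A[lt]; b <- B[lt]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant lower triangle: correlation undefined", call. = FALSE)
  if (method == "spearman") {
    # ranks of a permuted triangle are the identically permuted ranks, so
    # rank-transform once and use Pearson machinery throughout
    A[lt] <- rank(a); A[upper.tri(A)] <- t(A)[upper.tri(A)]
    B[lt] <- rank(b); B[upper.tri(B)] <- t(B)[upper.tri(B)]
    a <- A[lt]; b <- B[lt]
  }
  r <- stats::cor(a, b)
  permTriangles <- function(perms)
    vapply(seq_len(ncol(perms)), function(k) {
      p <- perms[, k]; B[p, p][lt]
    }, numeric(length(b)))
  if (exact) {
    rs <- drop(stats::cor(a, permTriangles(allPermutations(n))))
    p <- switch(alternative,
                two.sided = mean(abs(rs) >= abs(r) - 1e-12),
                greater = mean(rs >= r - 1e-12),
                less = mean(rs <= r + 1e-12))
    nperm <- length(rs)
  } else {
    perms <- withSeed(seed, vapply(seq_len(nperm), function(k)
      sample.int(n), integer(n)))
    rs <- drop(stats::cor(a, permTriangles(perms)))
    exceed <- switch(alternative,
                     two.sided = sum(abs(rs) >= abs(r) - 1e-12),
                     greater = sum(rs >= r - 1e-12),
                     less = sum(rs <= r + 1e-12))
    p <- (exceed + 1) / (nperm + 1)
  }
  list(r = r, p = p, nperm = nperm, method = method,
       alternative = alternative, seed = seed, exact = exact)
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the response matrix's lower triangle on the
#' predictor matrices' lower triangles (intercept included). Per-coefficient
#' p-values come from permuting the response matrix's rows and columns
#' simultaneously and re-estimating all coefficients each time (two-sided on
#' |b| with the +1 correction); the R-squared p-value is one-sided. With
#' `exact = TRUE` all n! relabelings are enumerated (n <= 8).
#'
#' @param response square symmetric response matrix.
#' @param predictors named list of square symmetric predictor matrices.
#' @param nperm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param exact enumerate all permutations.
#' @return list with `coefficients` (data.frame: term, estimate, p),
#'   `r_squared`, `p_r_squared`, `nperm`, `seed`.
#' @export
mrm <- function(response, predictors, nperm = 10000L, seed = NULL,
                exact = FALSE) {
  response <- checkSquareSymmetric(response, "response")
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("X", seq_along(predictors))
  predictors <- lapply(predictors, checkSquareSymmetric, name = "predictor")
  n <- nrow(response)
  lt <- lower.tri(response)
  y <- response[lt]
  X <- cbind(`(Intercept)` = 1,
             vapply(predictors, function(m) m[lt], numeric(sum(lt))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design: collinear predictor triangles", call. = FALSE)
  XtXinvXt <- solve(crossprod(X), t(X))
  beta <- drop(XtXinvXt %*% y)
  fitted <- drop(X %*% beta)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - fitted)^2) / tss

  permY <- function(p) response[p, p][lt]
  if (exact) {
    perms <- allPermutations(n)
    Yp <- apply(perms, 2, permY)
  } else {
    Yp <- withSeed(seed, vapply(seq_len(nperm), function(k)
      permY(sample.int(n)), numeric(length(y))))
  }
  Bp <- XtXinvXt %*% Yp                       # p x nperm
  Fp <- X %*% Bp
  rssP <- colSums((Yp - Fp)^2)
  tssP <- colSums(Yp^2) - colSums(Yp)^2 / length(y)
  r2p <- 1 - rssP / tssP
  m <- ncol(Yp)
  if (exact) {
    pCoef <- rowMeans(abs(Bp) >= abs(beta) - 1e-12)
    pR2 <- mean(r2p >= r2 - 1e-12)
  } else {
    pCoef <- (rowSums(abs(Bp) >= abs(beta) - 1e-12) + 1) / (m + 1)
    pR2 <- (sum(r2p >= r2 - 1e-12) + 1) / (m + 1)
  }
  list(coefficients = data.frame(term = colnames(X), estimate = beta,
                                 p = pCoef, row.names = NULL),
       r_squared = r2, p_r_squared = pR2, nperm = m, seed = seed,
       exact = exact)
}

#' Fit a Gaussian or Poisson GLM with diagnostics
#'
#' Thin wrapper over [stats::glm()] (IRLS) returning coefficient estimates,
#' standard errors and p-values, an R-squared (ordinary for Gaussian,
#' deviance-based pseudo for Poisson with log link), variance inflation
#' factors when there are two or more predictors, and a convergence flag.
#'
#' @param y response vector.
#' @param X numeric predictor matrix or data.frame (no intercept column).
#' @param family `"gaussian"` or `"poisson"` (log link).
#' @param offset optional offset vector on the link scale.
#' @return list with `coefficients` (data.frame), `r_squared`, `vif`,
#'   `converged`, `family`, `fit` (the glm object).
#' @export
glmFit <- function(y, X, family = c("gaussian", "poisson"), offset = NULL) {
  family <- match.arg(family)
  X <- as.data.frame(X)
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  if (length(y) <= ncol(X) + 1L)
    stop("need more observations than parameters", call. = FALSE)
  mm <- cbind(1, as.matrix(X))
  if (qr(mm)$rank < ncol(mm))
    stop("rank-deficient design matrix", call. = FALSE)
  fam <- if (family == "gaussian") stats::gaussian() else
    stats::poisson(link = "log")
  dat <- data.frame(.y = y, X, check.names = TRUE)
  fit <- stats::glm(.y ~ ., data = dat, family = fam, offset = offset,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "statistic", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  r2 <- if (family == "gaussian") {
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  } else 1 - fit$deviance / fit$null.deviance
  vifs <- if (ncol(X) >= 2L) vifScores(X) else NULL
  list(coefficients = co, r_squared = r2, vif = vifs,
       converged = fit$converged, family = family, fit = fit)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) where R^2_j is from regressing predictor j on all
#' the others (with intercept). Perfect collinearity yields Inf.
#'
#' @param X numeric matrix or data.frame with at least two columns.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vifScores <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (ncol(X) < 2L) stop("need at least two predictors", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Paired t-test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on differences d = x - y, df = n - 1,
#' two-sided p. Zero-variance differences are an error (undefined statistic).
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_difference`.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired vectors of length >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero-variance differences: t statistic undefined", call. = FALSE)
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
       mean_difference = mean(d))
}

#' Per-site relative changes of the impact covariates
#'
#' Relative change (current - historical) / historical of lake area, total
#' phosphorus, Secchi depth and fishery catch, computed on the raw scale
#' (relative changes can be negative, so level transforms do not apply here),
#' plus the lake centroids.
#'
#' @param covariates a [CovariateTable-class].
#' @param sites site order for the result (default: order in the table).
#' @param periods length-2 character: historical then current period label.
#' @return data.frame with columns site, area, tp, secchi, catch, lon, lat.
#' @export
impactChanges <- function(covariates, sites = NULL,
                          periods = c("historical", "current")) {
  d <- covariateData(covariates)
  if (is.null(sites)) sites <- unique(d$site)
  dh <- d[d$period == periods[1], ]; dc <- d[d$period == periods[2], ]
  rownames(dh) <- dh$site; rownames(dc) <- dc$site
  if (!all(sites %in% dh$site) || !all(sites %in% dc$site))
    stop("covariate table does not cover all sites in both periods",
         call. = FALSE)
  dh <- dh[sites, ]; dc <- dc[sites, ]
  out <- data.frame(site = sites)
  for (cc in covariateNumericCols)
    out[[sub("_.*$", "", cc)]] <- relativeChange(dh[[cc]], dc[[cc]])
  out$lon <- dh$lon; out$lat <- dh$lat
  out
}

#' Pairwise impact-change distance matrices from a covariate table
#'
#' For each impact covariate, the per-site relative change between periods
#' (see [impactChanges()]) is expanded to a site-pair matrix of absolute
#' differences |delta_i - delta_j| (`"absdiff"`, default) or pair means
#' (`"mean"`), then min-max standardized to \[0, 1\] so MRM coefficients are
#' comparable across impacts. The great-circle distance between lake
#' centroids (km, unstandardized) is returned alongside as `geo`.
#'
#' @inheritParams impactChanges
#' @param pairing `"absdiff"` or `"mean"`.
#' @param standardize min-max standardize each impact matrix (default TRUE).
#' @return named list of site x site matrices: area, tp, secchi, catch, geo.
#' @export
impactDistanceMatrices <- function(covariates, sites = NULL,
                                   periods = c("historical", "current"),
                                   pairing = c("absdiff", "mean"),
                                   standardize = TRUE) {
  pairing <- match.arg(pairing)
  ch <- impactChanges(covariates, sites, periods)
  sites <- ch$site
  out <- list()
  for (cc in c("area", "tp", "secchi", "catch")) {
    delta <- ch[[cc]]
    m <- if (pairing == "absdiff") abs(outer(delta, delta, `-`)) else
      outer(delta, delta, `+`) / 2
    if (standardize && diff(range(m[lower.tri(m)])) > 0) {
      r <- range(m[lower.tri(m)])
      m <- (m - r[1]) / diff(r)
    }
    diag(m) <- 0
    dimnames(m) <- list(sites, sites)
    out[[cc]] <- m
  }
  geo <- geosphere::distm(as.matrix(ch[, c("lon", "lat")]),
                          fun = geosphere::distHaversine) / 1000
  dimnames(geo) <- list(sites, sites)
  out$geo <- geo
  out
}
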