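#' @include AllClasses.R
NULL

#' Encode categorical traits as a numeric species-by-feature matrix
#'
#' `"onehot"` produces one 0/1 indicator column per trait level. `"gower"`
#' rescales the same indicators by 1/sqrt(2 T) (T traits) so that squared
#' Euclidean distance between rows equals the simple-matching Gower
#' dissimilarity (fraction of mismatching traits).
#'
#' @param traits a [TraitTable-class].
#' @param scheme `"onehot"` (default) or `"gower"`.
#' @return numeric matrix, species rows, one column per trait level; carries
#'   attributes `scheme` and `n_traits`.
#' @export
encodeTraits <- function(traits, scheme = c("onehot", "gower")) {
  scheme <- match.arg(scheme)
  td <- traitData(traits)
  voc <- vocabulary(traits)
  cols <- lapply(names(voc), function(nm) {
    m <- outer(as.character(td[[nm]]), voc[[nm]], `==`) * 1
    colnames(m) <- paste(nm, voc[[nm]], sep = ".")
    m
  })
  enc <- do.call(cbind, cols)
  rownames(enc) <- rownames(td)
  if (scheme == "gower") enc <- enc / sqrt(2 * length(voc))
  structure(enc, scheme = scheme, n_traits = length(voc))
}

#' Functional distance matrix between species
#'
#' `"euclidean"` is the ordinary Euclidean distance between encoded rows (the
#' default trait-space metric). `"gower"` is the simple-matching Gower
#' dissimilarity: the fraction of traits on which two species differ,
#' recovered from the encoding regardless of scheme.
#'
#' @param encoded matrix from [encodeTraits()].
#' @param metric `"euclidean"` or `"gower"`.
#' @return symmetric distance matrix with zero diagonal (class `matrix`).
#' @export
traitDistance <- function(encoded, metric = c("euclidean", "gower")) {
  metric <- match.arg(metric)
  if (nrow(encoded) < 2L)
    stop("need at least two species to compute distances", call. = FALSE)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(encoded))
  } else {
    nt <- attr(encoded, "n_traits")
    if (is.null(nt)) stop("encoded matrix lacks trait metadata", call. = FALSE)
    sq <- as.matrix(stats::dist(encoded))^2
    scale <- if (identical(attr(encoded, "scheme"), "gower")) 1 else 1 / (2 * nt)
    d <- sq * scale
  }
  diag(d) <- 0
  d
}

#' Build the functional space by principal coordinates analysis
#'
#' Runs PCoA (via \code{ape::pcoa}) on the species functional distance matrix
#' and retains the first \code{m} positive-eigenvalue axes, scaled by the
#' square root of their eigenvalues so inter-point Euclidean distances
#' approximate the input distances. Axis signs are fixed by forcing the
#' largest-magnitude score on each axis positive, so runs are reproducible.
#' Negative eigenvalues are excluded from both the coordinates and the
#' quality denominator unless a correction is requested.
#'
#' @param dist symmetric distance matrix (as from [traitDistance()]) or a
#'   `dist` object.
#' @param m number of axes to retain (default 3). If fewer positive
#'   eigenvalues exist, m is reduced with a warning.
#' @param correction `"none"` (default), `"lingoes"` or `"cailliez"` negative
#'   eigenvalue correction.
#' @return a [FunctionalSpace-class].
#' @export
buildFunctionalSpace <- function(dist, m = 3L, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  dm <- as.matrix(dist)
  if (nrow(dm) < 2L) stop("need at least two species", call. = FALSE)
  if (m >= nrow(dm)) stop("m must be smaller than the number of species",
                          call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("sp", seq_len(nrow(dm)))
  pc <- ape::pcoa(stats::as.dist(dm), correction = correction)
  eig <- if (correction != "none" && "Corr_eig" %in% colnames(pc$values))
    pc$values$Corr_eig else pc$values$Eigenvalues
  vec <- if (!is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
  tol <- max(abs(eig)) * 1e-8
  npos <- sum(eig > tol)
  if (npos == 0L) stop("degenerate space: no positive eigenvalue", call. = FALSE)
  if (m > npos) {
    warning(sprintf("only %d positive eigenvalue(s); reducing m from %d", npos, m),
            call. = FALSE)
    m <- npos
  }
  coords <- vec[, seq_len(m), drop = FALSE]
  # reproducible axis orientation
  for (k in seq_len(m)) {
    piv <- which.max(abs(coords[, k]))
    if (coords[piv, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- labels
  colnames(coords) <- paste0("PcoA", seq_len(m))
  pos <- eig[eig > tol]
  new("FunctionalSpace", coordinates = coords,
      eigenvalues = sort(eig, decreasing = TRUE),
      quality = sum(pos[seq_len(m)]) / sum(pos),
      metric = if (correction == "none") "euclidean" else
        paste0("euclidean+", correction))
}

#' Fraction of functional variation captured by the leading axes
#'
#' Sum of the first m positive eigenvalues divided by the sum of all positive
#' eigenvalues; negative eigenvalues are ignored.
#'
#' @param space a [FunctionalSpace-class], or a numeric eigenvalue vector.
#' @param m number of leading axes.
#' @return fraction in \[0, 1\].
#' @export
spaceQuality <- function(space, m) {
  eig <- if (is(space, "FunctionalSpace")) eigenvalues(space) else
    sort(as.numeric(space), decreasing = TRUE)
  tol <- max(abs(eig)) * 1e-12
  pos <- eig[eig > tol]
  if (!length(pos)) stop("degenerate space: no positive eigenvalue", call. = FALSE)
  sum(pos[seq_len(min(m, length(pos)))]) / sum(pos)
}
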