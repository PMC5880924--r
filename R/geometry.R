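# Convex-hull geometry in 1-3 dimensions: hull construction, volume, facet
# inequalities, and pairwise hull intersection. Used for functional richness
# (hull volume) and functional beta diversity (hull overlap). Dimensions
# above 3 are not supported: the functional space retains 3 axes by default
# and the overlap geometry is exact only for d <= 3 here.

crossProd <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# scale of a point cloud, used for relative tolerances
cloudScale <- function(P) {
  if (nrow(P) == 0L) return(1)
  s <- max(apply(P, 2, function(x) diff(range(x))), 0)
  if (s == 0) 1 else s
}

# Build the convex hull of points P (n x d, d in 1:3).
# Returns list(dim, volume, degenerate, vertices (row indices into P),
# normals (k x d unit rows), offsets (k), facets) where the inequality
# system is normals %*% x <= offsets.
convexHull <- function(P, tol = NULL) {
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  d <- ncol(P)
  if (!d %in% 1:3) stop("convex hulls supported for 1-3 dimensions only",
                        call. = FALSE)
  if (is.null(tol)) tol <- 1e-9 * cloudScale(P)
  P <- unique(P)
  if (nrow(P) == 0L) return(degenerateHull(P, d))
  switch(d, hull1d(P, tol), hull2d(P, tol), hull3d(P, tol))
}

hull1d <- function(P, tol) {
  lo <- min(P[, 1]); hi <- max(P[, 1])
  deg <- (hi - lo) <= tol
  list(dim = 1L, volume = if (deg) 0 else hi - lo, degenerate = deg,
       vertices = if (deg) matrix(lo, 1, 1) else matrix(c(lo, hi), 2, 1),
       normals = matrix(c(1, -1), 2, 1), offsets = c(hi, -lo))
}

hull2d <- function(P, tol) {
  if (nrow(P) < 3L) return(degenerateHull(P, 2L))
  idx <- grDevices::chull(P)
  V <- P[idx, , drop = FALSE]
  # signed shoelace area; ensure counter-clockwise ordering
  x <- V[, 1]; y <- V[, 2]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) { V <- V[rev(seq_len(nrow(V))), , drop = FALSE]; a2 <- -a2 }
  area <- a2 / 2
  if (area <= tol^2 || nrow(V) < 3L) return(degenerateHull(P, 2L))
  nxt <- c(seq_len(nrow(V))[-1], 1L)
  e <- V[nxt, , drop = FALSE] - V
  # CCW polygon: outward normal of edge (dx,dy) is (dy,-dx)
  N <- cbind(e[, 2], -e[, 1])
  len <- sqrt(rowSums(N^2))
  keep <- len > 0
  N <- N[keep, , drop = FALSE] / len[keep]
  list(dim = 2L, volume = area, degenerate = FALSE, vertices = V,
       normals = N, offsets = rowSums(N * V[keep, , drop = FALSE]))
}

degenerateHull <- function(P, d) {
  list(dim = d, volume = 0, degenerate = TRUE,
       vertices = P, normals = NULL, offsets = NULL)
}

# Incremental hull with a consistency safeguard: candidate point sets from
# intersections are near-coplanar by construction, and a visibility tolerance
# close to the coplanarity scale can break the horizon. The signed facet
# volumes w.r.t. an interior point must all be nonnegative for a watertight
# outward-oriented surface; on violation the hull is rebuilt with an
# escalated tolerance.
hull3d <- function(P, tol) {
  for (f in c(1, 1e2, 1e4)) {
    h <- hull3dOnce(P, tol * f)
    if (h$degenerate || isTRUE(attr(h, "consistent"))) return(h)
  }
  h
}

hull3dOnce <- function(P, tol) {
  n <- nrow(P)
  if (n < 4L) return(degenerateHull(P, 3L))
  # initial simplex: four affinely independent points
  i1 <- which.min(P[, 1])
  d2 <- rowSums(sweep(P, 2, P[i1, ])^2)
  i2 <- which.max(d2)
  if (sqrt(d2[i2]) <= tol) return(degenerateHull(P, 3L))
  u <- (P[i2, ] - P[i1, ]) / sqrt(d2[i2])
  rel <- sweep(P, 2, P[i1, ])
  perp <- rel - outer(drop(rel %*% u), u)
  d3 <- rowSums(perp^2)
  i3 <- which.max(d3)
  if (sqrt(d3[i3]) <= tol) return(degenerateHull(P, 3L))
  nrm0 <- crossProd(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  nrm0 <- nrm0 / sqrt(sum(nrm0^2))
  h <- abs(drop(rel %*% nrm0))
  i4 <- which.max(h)
  if (h[i4] <= tol) return(degenerateHull(P, 3L))

  o <- colMeans(P[c(i1, i2, i3, i4), , drop = FALSE])  # strictly interior
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    nn <- crossProd(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    if (sum(nn * o) > sum(nn * P[f[1], ])) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  facePlane <- function(f) {
    nn <- crossProd(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    ln <- sqrt(sum(nn^2))
    if (ln <= tol^2) return(rep(NA_real_, 4))
    nn <- nn / ln
    c(nn, sum(nn * P[f[1], ]))
  }
  planes <- t(apply(faces, 1, facePlane))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    pt <- P[p, ]
    vis <- drop(planes[, 1:3, drop = FALSE] %*% pt) - planes[, 4] > tol
    if (!any(vis)) next
    visF <- faces[vis, , drop = FALSE]
    dirEdges <- rbind(visF[, c(1, 2)], visF[, c(2, 3)], visF[, c(3, 1)])
    keys <- paste(dirEdges[, 1], dirEdges[, 2])
    revKeys <- paste(dirEdges[, 2], dirEdges[, 1])
    horizon <- dirEdges[!(keys %in% revKeys), , drop = FALSE]
    newFaces <- cbind(horizon, p)
    newPlanes <- t(apply(newFaces, 1, facePlane))
    ok <- !is.na(newPlanes[, 4])
    faces <- rbind(faces[!vis, , drop = FALSE], newFaces[ok, , drop = FALSE])
    planes <- rbind(planes[!vis, , drop = FALSE], newPlanes[ok, , drop = FALSE])
  }

  vidx <- sort(unique(as.vector(faces)))
  o <- colMeans(P[vidx, , drop = FALSE])
  signed <- vapply(seq_len(nrow(faces)), function(k) {
    f <- faces[k, ]
    a <- P[f[1], ] - o; b <- P[f[2], ] - o; cc <- P[f[3], ] - o
    sum(a * crossProd(b, cc)) / 6
  }, numeric(1))
  consistent <- all(signed >= -tol * cloudScale(P)^2)
  structure(
    list(dim = 3L, volume = sum(abs(signed)), degenerate = FALSE,
         vertices = P[vidx, , drop = FALSE], facets = faces,
         facetPoints = P,
         normals = planes[, 1:3, drop = FALSE], offsets = planes[, 4]),
    consistent = consistent)
}

# TRUE for each row of X inside (or on, within tol) the hull
pointsInHull <- function(X, hull, tol) {
  if (hull$degenerate) return(rep(FALSE, nrow(X)))
  E <- X %*% t(hull$normals)
  rowSums(E > matrix(hull$offsets + tol, nrow(X), length(hull$offsets),
                     byrow = TRUE)) == 0
}

# undirected vertex-pair edges of a hull, as a 2-column matrix of point rows
hullEdges <- function(hull) {
  d <- hull$dim
  V <- hull$vertices
  if (d == 1L) return(matrix(c(1L, nrow(V)), 1, 2))
  if (d == 2L) {
    n <- nrow(V)
    return(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  }
  f <- hull$facets
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

# vertex coordinates addressed by hullEdges' indices
edgeCoords <- function(hull) {
  if (hull$dim == 3L) hull$facetPoints else hull$vertices
}

#' Convex hull volume of a point cloud
#'
#' Volume (3-D), area (2-D) or length (1-D) of the convex hull. Returns 0
#' with a `degenerate` attribute when the points do not span the full
#' dimension (fewer than d+1 points, or affinely dependent).
#'
#' @param points numeric matrix, one row per point, 1-3 columns.
#' @return nonnegative volume; attribute `degenerate` is TRUE when the hull
#'   is flat.
#' @export
hullVolume <- function(points) {
  h <- convexHull(points)
  structure(h$volume, degenerate = h$degenerate)
}

#' Volume of the intersection of two convex hulls
#'
#' Exact intersection volume for convex polytopes in 1-3 dimensions. The
#' intersection's vertices are enumerated as (i) vertices of each hull lying
#' inside the other and (ii) crossings of one hull's edges with the other's
#' facets; the volume is the convex-hull volume of those candidates. Disjoint
#' hulls give 0; a degenerate input hull gives NA (pair not measurable).
#'
#' @param x,y numeric point matrices with the same number of columns (1-3).
#' @return intersection volume, 0 if disjoint, NA if either hull degenerate.
#' @export
intersectionVolume <- function(x, y) {
  d <- ncol(x)
  if (ncol(y) != d) stop("point sets must share the dimension", call. = FALSE)
  scale <- max(cloudScale(as.matrix(x)), cloudScale(as.matrix(y)))
  tol <- 1e-9 * scale
  ha <- convexHull(x); hb <- convexHull(y)
  if (ha$degenerate || hb$degenerate) return(NA_real_)
  hullIntersectionVolume(ha, hb, tol)
}

hullIntersectionVolume <- function(ha, hb, tol) {
  inTol <- 100 * tol  # slack for boundary membership
  cand <- rbind(
    ha$vertices[pointsInHull(ha$vertices, hb, inTol), , drop = FALSE],
    hb$vertices[pointsInHull(hb$vertices, ha, inTol), , drop = FALSE],
    edgeFacetCrossings(ha, hb, inTol),
    edgeFacetCrossings(hb, ha, inTol))
  if (is.null(cand) || nrow(cand) <= ha$dim) return(0)
  cand <- unique(cand)
  if (nrow(cand) <= ha$dim) return(0)
  convexHull(cand)$volume
}

# crossing points of hull A's edges with hull B's facet planes that lie in
# both hulls
edgeFacetCrossings <- function(ha, hb, tol) {
  if (is.null(hb$normals)) return(NULL)
  E <- hullEdges(ha)
  V <- edgeCoords(ha)
  out <- vector("list", nrow(E))
  for (k in seq_len(nrow(E))) {
    p <- V[E[k, 1], ]; q <- V[E[k, 2], ]
    dq <- q - p
    den <- drop(hb$normals %*% dq)
    num <- hb$offsets - drop(hb$normals %*% p)
    t <- ifelse(abs(den) > 1e-14, num / den, NA_real_)
    t <- t[!is.na(t) & t >= 0 & t <= 1]
    if (!length(t)) next
    X <- matrix(p, length(t), length(p), byrow = TRUE) + outer(t, dq)
    keep <- pointsInHull(X, ha, tol) & pointsInHull(X, hb, tol)
    if (any(keep)) out[[k]] <- X[keep, , drop = FALSE]
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) NULL else do.call(rbind, out)
}
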