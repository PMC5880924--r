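# Independent oracles: written from the definitions, never calling the code
# paths they check.

# enumerate all permutations of 1..n as a list (independent of the package's
# enumerator: iterative insertion construction)
oraclePermutations <- function(n) {
  perms <- list(1L)
  for (k in 2L:n) {
    out <- list()
    for (p in perms)
      for (pos in 0:(k - 1L))
        out[[length(out) + 1L]] <- append(p, k, after = pos)
    perms <- out
  }
  perms
}

# exhaustive Mantel p-value: relabel B by every permutation, two-sided on |r|
oracleMantelExact <- function(A, B, method = "pearson") {
  lt <- lower.tri(A)
  r0 <- cor(A[lt], B[lt], method = method)
  rs <- vapply(oraclePermutations(nrow(A)), function(p)
    cor(A[lt], B[p, p][lt], method = method), numeric(1))
  list(r = r0, p = mean(abs(rs) >= abs(r0) - 1e-12))
}

# exhaustive MRM per-coefficient p-values (two-sided on |b|)
oracleMrmExact <- function(response, predictors) {
  lt <- lower.tri(response)
  X <- cbind(1, vapply(predictors, function(m) m[lt], numeric(sum(lt))))
  bhat <- solve(crossprod(X), crossprod(X, response[lt]))
  Bs <- vapply(oraclePermutations(nrow(response)), function(p)
    drop(solve(crossprod(X), crossprod(X, response[p, p][lt]))),
    numeric(ncol(X)))
  list(coef = drop(bhat),
       p = rowMeans(abs(Bs) >= abs(drop(bhat)) - 1e-12))
}

# Baselga-family partition from the max/min closed forms (a different
# algebraic route than total - turnover)
oraclePartition <- function(a, b, c, family = "jaccard") {
  mn <- min(b, c); mx <- max(b, c)
  if (family == "jaccard") {
    list(total = (b + c) / (a + b + c),
         turnover = if (mn == 0) 0 else 2 * mn / (a + 2 * mn),
         nestedness = ((mx - mn) / (a + b + c)) * (a / (a + 2 * mn)))
  } else {
    list(total = (b + c) / (2 * a + b + c),
         turnover = if (mn == 0) 0 else mn / (a + mn),
         nestedness = ((mx - mn) / (2 * a + b + c)) * (a / (a + mn)))
  }
}

## ---- random polytopes with membership tests independent of the package ----

# a random simplex (tetrahedron): membership via barycentric coordinates
randomSimplex <- function(scale = 1, shift = 0) {
  V <- matrix(rnorm(12), 4, 3) * scale + rep(shift, each = 4)
  while (abs(det(t(V[-1, ]) - V[1, ])) < 1e-3)
    V <- matrix(rnorm(12), 4, 3) * scale + rep(shift, each = 4)
  list(vertices = V,
       contains = function(X) {
         M <- t(V[-1, ]) - V[1, ]
         lam <- t(solve(M, t(sweep(X, 2, V[1, ]))))
         apply(lam, 1, function(l) all(l >= -1e-12)) &
           rowSums(lam) <= 1 + 1e-12
       })
}

# a random parallelepiped (affine image of the unit cube): membership by
# inverting the affine map
randomParallelepiped <- function(scale = 1, shift = 0) {
  A <- matrix(rnorm(9), 3, 3) * scale
  while (abs(det(A)) < 1e-3) A <- matrix(rnorm(9), 3, 3) * scale
  b <- rnorm(3) + shift
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  list(vertices = corners %*% t(A) + rep(b, each = 8),
       contains = function(X) {
         U <- t(solve(A, t(sweep(X, 2, b))))
         apply(U >= -1e-12 & U <= 1 + 1e-12, 1, all)
       })
}

# Monte Carlo rejection-sampling estimate of the intersection volume of two
# polytopes carrying independent membership tests
oracleMcIntersection <- function(p1, p2, n = 1e5) {
  lo <- pmax(apply(p1$vertices, 2, min), apply(p2$vertices, 2, min))
  hi <- pmin(apply(p1$vertices, 2, max), apply(p2$vertices, 2, max))
  if (any(hi <= lo)) return(list(volume = 0, se = 0))
  X <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  inside <- p1$contains(X) & p2$contains(X)
  vbox <- prod(hi - lo)
  phat <- mean(inside)
  # binomial SE with a floor at the sampling resolution, so zero-hit runs on
  # tiny true overlaps do not report an impossible SE of exactly 0
  se <- vbox * sqrt(max(phat * (1 - phat), 1 / n) / n)
  list(volume = vbox * phat, se = se)
}

## ---- small fixtures ----

# a small paired-assemblage fixture built by hand
toyPaired <- function() {
  h <- matrix(c(1,1,1,0,0,
                0,1,1,1,0,
                1,0,0,1,1), 3, 5, byrow = TRUE,
              dimnames = list(c("L1","L2","L3"), paste0("s", 1:5)))
  cu <- h
  cu["L1", "s1"] <- 0
  cu["L3", c("s4","s5")] <- 0
  alignPeriods(assemblageMatrix(h, "historical"),
               assemblageMatrix(cu, "current"))
}

# a fast small scenario for property tests
smallScenario <- function(seed = 1, ...) {
  syntheticScenario(n_sites = 10L, pool_size = 60L, mean_richness = 16,
                    seed = seed, ...)
}
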