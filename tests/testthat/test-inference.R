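test_that("transform-standardize maps to [0,1] with the right transforms", {
  expect_equal(transformStandardize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(transformStandardize(c(1, 10, 100), "log"), c(0, 0.5, 1))
  expect_equal(transformStandardize(c(0, 1, 4), "sqrt"), c(0, 0.5, 1))
  expect_error(transformStandardize(c(5, 5, 5)), "constant")
  expect_error(transformStandardize(c(-1, 2), "log"), "positive")
})

test_that("relative change is (curr - hist)/hist", {
  expect_equal(relativeChange(100, 60), -0.40)
  expect_equal(relativeChange(3, 3), 0)
  expect_equal(relativeChange(2, 4), 1)
  expect_error(relativeChange(0, 1), "zero baseline")
})

test_that("mantel statistic hits its bounds on degenerate relations", {
  withr::with_seed(2, {
    A <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    m <- mantelTest(A, A, nperm = 199, seed = 1)
    expect_equal(m$r, 1)
    expect_equal(m$p, 1 / 200)               # smallest attainable
    # monotone decreasing transform: spearman r = -1
    B <- max(A) - A; diag(B) <- 0
    ms <- mantelTest(A, B, method = "spearman", nperm = 99, seed = 1)
    expect_equal(ms$r, -1)
    C <- matrix(5, 10, 10)
    expect_error(mantelTest(A, C, nperm = 9), "constant lower triangle")
  })
})

test_that("exact mantel p-values equal exhaustive enumeration", {
  withr::with_seed(31, {
    for (k in 1:5) {
      A <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
      B <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
      m <- mantelTest(A, B, exact = TRUE)
      o <- oracleMantelExact(A, B)
      expect_equal(m$nperm, 24L)
      expect_equal(m$r, o$r, tolerance = 1e-12)
      expect_equal(m$p, o$p, tolerance = 1e-12)
    }
    # 5 sites too
    A <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
    B <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
    expect_equal(mantelTest(A, B, exact = TRUE)$p, oracleMantelExact(A, B)$p)
  })
})

test_that("mantel agrees with vegan's one-sided test on the statistic", {
  skip_if_not_installed("vegan")
  withr::with_seed(13, {
    X <- matrix(rnorm(30), 15, 2)
    A <- as.matrix(dist(X))
    B <- as.matrix(dist(X + rnorm(30, sd = 0.5)))
    m <- mantelTest(A, B, nperm = 999, seed = 5, alternative = "greater")
    v <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
    expect_equal(m$r, unname(v$statistic), tolerance = 1e-12)
    expect_lt(abs(m$p - v$signif), 0.03)
  })
})

test_that("mrm recovers exact linear structure and matches enumeration", {
  withr::with_seed(17, {
    P1 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    resp <- 3 * P1
    m <- mrm(resp, list(p1 = P1), nperm = 99, seed = 1)
    expect_equal(m$coefficients$estimate[2], 3, tolerance = 1e-10)
    expect_equal(m$r_squared, 1, tolerance = 1e-10)
    # exhaustive enumeration on 4 sites
    A <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
    B <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
    C <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
    me <- mrm(A, list(b = B, c = C), exact = TRUE)
    oe <- oracleMrmExact(A, list(B, C))
    expect_equal(me$coefficients$estimate, unname(oe$coef), tolerance = 1e-10)
    expect_equal(me$coefficients$p, unname(oe$p), tolerance = 1e-12)
    # collinear triangles are rejected
    expect_error(mrm(A, list(b = B, b2 = 2 * B), nperm = 9),
                 "rank-deficient")
  })
})

test_that("mrm p-values are roughly uniform under independence", {
  withr::with_seed(23, {
    ps <- replicate(60, {
      A <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
      B <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
      mrm(A, list(b = B), nperm = 99)$coefficients$p[2]
    })
    expect_gt(median(ps), 0.3)
    expect_lt(median(ps), 0.7)
  })
})

test_that("glm wrapper matches closed forms", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- glmFit(2 * x, data.frame(x = x), family = "gaussian")
  expect_equal(g$coefficients$estimate[2], 2, tolerance = 1e-10)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  # poisson with binary predictor: intercept ln 2, slope ln 2 from group
  # means 2 and 4 (closed-form MLE)
  y <- c(rep(2, 50), rep(4, 50))
  xb <- rep(c(0, 1), each = 50)
  gp <- glmFit(y, data.frame(x = xb), family = "poisson")
  expect_equal(gp$coefficients$estimate, c(log(2), log(2)), tolerance = 1e-8)
  expect_true(gp$converged)
  expect_error(glmFit(y, data.frame(a = xb, b = xb), family = "poisson"),
               "rank-deficient")
})

test_that("glm recovers simulated coefficients within 3 SE most of the time", {
  withr::with_seed(41, {
    hit <- replicate(60, {
      x <- rnorm(120)
      y <- rpois(120, exp(0.5 + 0.4 * x))
      g <- glmFit(y, data.frame(x = x), family = "poisson")
      abs(g$coefficients$estimate[2] - 0.4) <= 3 * g$coefficients$se[2]
    })
    expect_gte(mean(hit), 0.95)
  })
})

test_that("variance inflation factors follow the 1/(1-R2) definition", {
  withr::with_seed(9, {
    # design orthogonal to the intercept and to itself: all VIF exactly 1
    X <- qr.Q(qr(cbind(1, matrix(rnorm(100), 20, 5))))[, -1]
    expect_equal(unname(vifScores(X)), rep(1, 5), tolerance = 1e-8)
    # constructed R2 = 0.75 -> VIF = 4
    x1 <- rnorm(2000)
    e <- rnorm(2000)
    x2 <- x1 * sqrt(0.75) + e * sqrt(0.25) / sd(e) * 1  # approx R2 0.75
    v <- vifScores(cbind(x1 = x1, x2 = x2))
    fitR2 <- summary(lm(x2 ~ x1))$r.squared
    expect_equal(unname(v["x2"]), 1 / (1 - fitR2), tolerance = 1e-8)
    expect_equal(unname(v["x2"]), 4, tolerance = 0.4)
    # duplicated predictor: infinite VIF flagged
    expect_true(is.infinite(vifScores(cbind(a = x1, b = x1))["a"]))
  })
})

test_that("vif matches car on a shared design", {
  skip_if_not_installed("car")
  withr::with_seed(3, {
    X <- as.data.frame(matrix(rnorm(200), 50, 4))
    y <- rnorm(50)
    ours <- vifScores(X)
    theirs <- car::vif(lm(y ~ ., data = X))
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
  })
})

test_that("paired t matches the hand computation", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)       # d = 1,2,3
  r <- pairedTTest(x, y)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t, 3.4641016, tolerance = 1e-6)
  expect_identical(r$df, 2L)
  expect_equal(r$p, stats::t.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-12)
  # sign flip negates t
  expect_equal(pairedTTest(y, x)$t, -r$t)
  expect_error(pairedTTest(x, x), "zero-variance")
})

test_that("impact matrices cover the covariates and include geography", {
  cov <- generateCovariates(8, seed = 2)
  dm <- impactDistanceMatrices(cov)
  expect_identical(names(dm), c("area", "tp", "secchi", "catch", "geo"))
  for (m in dm) {
    expect_identical(dim(m), c(8L, 8L))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  # standardized impact matrices live in [0,1]
  expect_equal(range(dm$area[lower.tri(dm$area)]), c(0, 1))
  ch <- impactChanges(cov)
  expect_identical(names(ch), c("site", "area", "tp", "secchi", "catch",
                                "lon", "lat"))
})
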