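test_that("species richness counts presences", {
  expect_identical(speciesRichness(c(1, 0, 1, 1)), 3L)
  expect_identical(speciesRichness(rep(0, 10)), 0L)
  expect_identical(speciesRichness(rep(1, 275)), 275L)
  am <- assemblageMatrix(matrix(c(1,0,1, 0,0,0), 2, 3, byrow = TRUE,
    dimnames = list(c("A","B"), c("s1","s2","s3"))))
  expect_identical(speciesRichness(am), c(A = 2L, B = 0L))
})

test_that("taxonomic components are plain set arithmetic", {
  x <- c(s1=1,s2=1,s3=1,s4=1,s5=1,s6=0)
  y <- c(s1=0,s2=0,s3=0,s4=1,s5=1,s6=1)
  expect_identical(taxonomicComponents(x, y)[c("a","b","c")],
                   list(a = 2L, b = 3L, c = 1L))
  r <- c(s1=1,s2=1,s3=1,s4=0,s5=0,s6=0)
  expect_identical(taxonomicComponents(r, r)[c("a","b","c")],
                   list(a = 3L, b = 0L, c = 0L))
  d <- c(s1=0,s2=0,s3=0,s4=1,s5=1,s6=1)
  expect_identical(taxonomicComponents(r, d)[c("a","b","c")],
                   list(a = 0L, b = 3L, c = 3L))
})

test_that("the partition matches the closed-form oracle on fixed triples", {
  p <- betaPartition(2, 3, 1)
  o <- oraclePartition(2, 3, 1)
  expect_equal(p$total, 2/3, tolerance = 1e-12)
  expect_equal(p$turnover, 0.5, tolerance = 1e-12)
  expect_equal(p$nestedness, o$nestedness, tolerance = 1e-12)
  expect_equal(p$nestedness, 1/6, tolerance = 1e-12)
  # nested pair: no turnover
  pn <- betaPartition(3, 4, 0)
  expect_equal(pn$turnover, 0)
  expect_equal(pn$nestedness, 4/7)
  expect_equal(pn$total, 4/7)
  # disjoint equal pair: pure turnover
  pd <- betaPartition(0, 5, 5)
  expect_equal(pd$total, 1); expect_equal(pd$turnover, 1)
  expect_equal(pd$nestedness, 0)
  expect_error(betaPartition(0, 0, 0), "empty pair")
})

test_that("partition identity and oracle agreement hold over random triples", {
  withr::with_seed(99, {
    for (fam in c("jaccard", "sorensen")) {
      a <- runif(300, 0, 10); b <- runif(300, 0, 10); cc <- runif(300, 0, 10)
      for (k in seq_len(300)) {
        p <- betaPartition(a[k], b[k], cc[k], family = fam)
        o <- oraclePartition(a[k], b[k], cc[k], family = fam)
        expect_lt(abs(p$total - (p$turnover + p$nestedness)), 1e-10)
        expect_lt(abs(p$turnover - o$turnover), 1e-10)
        expect_lt(abs(p$nestedness - o$nestedness), 1e-10)
        expect_true(p$turnover >= 0 && p$turnover <= p$total &&
                      p$total <= 1)
        if (p$total > 0)
          expect_lt(abs(p$turnover_contribution +
                          p$nestedness_contribution - 1), 1e-10)
      }
    }
  })
})

test_that("functional richness is the pool-standardized hull volume", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  halfbox <- as.matrix(expand.grid(0:1, 0:1, c(0, 0.5)))
  co <- unique(rbind(cube, halfbox))
  rownames(co) <- paste0("s", seq_len(nrow(co)))
  fs <- new("FunctionalSpace", coordinates = co, eigenvalues = c(3, 2, 1),
            quality = 1, metric = "euclidean")
  pool <- rownames(co)
  expect_equal(functionalRichness(pool, fs), 1)
  expect_equal(functionalRichness(pool[1], fs), 0)     # single species
  # an assemblage filling exactly half the pool hull
  halfIds <- rownames(co)[apply(co, 1, function(p) p[3] <= 0.5)]
  expect_equal(functionalRichness(halfIds, fs), 0.5)
  expect_error(functionalRichness("nope", fs), "missing functional")
})

test_that("functional components follow hull arithmetic", {
  co <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
              as.matrix(expand.grid(0:1, 0:1, 0:1)) + 0.5)
  rownames(co) <- paste0("s", 1:16)
  fs <- new("FunctionalSpace", coordinates = co, eigenvalues = c(3, 2, 1),
            quality = 1, metric = "euclidean")
  x <- stats::setNames(c(rep(1, 8), rep(0, 8)), rownames(co))
  y <- stats::setNames(c(rep(0, 8), rep(1, 8)), rownames(co))
  fc <- functionalComponents(x, y, fs)
  expect_equal(fc$a, 0.125)
  expect_equal(fc$b, 0.875); expect_equal(fc$c, 0.875)
  # identical point sets: pure overlap
  fi <- functionalComponents(x, x, fs)
  expect_equal(fi$a, 1); expect_equal(fi$b, 0); expect_equal(fi$c, 0)
  # degenerate member flags the pair
  z <- stats::setNames(c(1, 1, rep(0, 14)), rownames(co))
  expect_true(is.na(functionalComponents(x, z, fs)$a))
})

test_that("pairwiseBeta builds one record per unordered pair", {
  occ <- matrix(rbinom(4 * 12, 1, 0.5), 4, 12,
                dimnames = list(paste0("L", 1:4), paste0("s", 1:12)))
  occ[1, ] <- c(rep(1, 5), rep(0, 7))
  occ[2, ] <- c(rep(0, 2), rep(1, 3), rep(0, 7))  # richness 5 vs 3
  am <- assemblageMatrix(occ)
  pb <- pairwiseBeta(am)
  expect_identical(nrow(pb), 6L)
  expect_equal(pb$richness_ratio_tax[1], 3/5)
  expect_lt(max(abs(pb$tax_total - (pb$tax_turnover + pb$tax_nestedness)),
                na.rm = TRUE), 1e-10)
  # permutation invariance to species order
  perm <- sample(ncol(occ))
  pb2 <- pairwiseBeta(assemblageMatrix(occ[, perm]))
  expect_equal(pb2$tax_total, pb$tax_total)
})

test_that("adding a shared species never increases taxonomic dissimilarity", {
  withr::with_seed(21, {
    for (k in 1:20) {
      x <- rbinom(30, 1, 0.4); y <- rbinom(30, 1, 0.4)
      if (sum(x) == 0 || sum(y) == 0) next
      free <- which(x == 0 & y == 0)
      if (!length(free)) next
      c0 <- taxonomicComponents(x, y)
      d0 <- betaPartition(c0$a, c0$b, c0$c)$total
      x[free[1]] <- 1; y[free[1]] <- 1
      c1 <- taxonomicComponents(x, y)
      d1 <- betaPartition(c1$a, c1$b, c1$c)$total
      expect_lte(d1, d0 + 1e-12)
    }
  })
})

test_that("functional dissimilarity is invariant to rigid rotation", {
  withr::with_seed(5, {
    co <- matrix(rnorm(90), 30, 3, dimnames = list(paste0("s", 1:30), NULL))
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    occ <- matrix(rbinom(90, 1, 0.5), 3, 30,
                  dimnames = list(paste0("L", 1:3), rownames(co)))
    occ[rowSums(occ) < 4, ] <- 1
    fs1 <- new("FunctionalSpace", coordinates = co, eigenvalues = c(3,2,1),
               quality = 1, metric = "euclidean")
    fs2 <- new("FunctionalSpace", coordinates = co %*% q,
               eigenvalues = c(3,2,1), quality = 1, metric = "euclidean")
    b1 <- pairwiseBeta(assemblageMatrix(occ), fs1)
    b2 <- pairwiseBeta(assemblageMatrix(occ), fs2)
    expect_equal(b1$fun_total, b2$fun_total, tolerance = 1e-6)
  })
})
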