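test_that("partial correlation matches its defining special cases", {
  set.seed(1)
  y <- rnorm(50); z <- rnorm(50)
  expect_equal(partialCorr(y, z, NULL), cor(y, z), tolerance = 1e-12)
  X <- matrix(rnorm(100), 50, 2)
  expect_equal(partialCorr(y, y, X), 1, tolerance = 1e-12)
  ## shared driver fully explained by the covariate
  x1 <- rnorm(500)
  ya <- x1 + rnorm(500); za <- x1 + rnorm(500)
  expect_lt(abs(partialCorr(ya, za, cbind(x1))), 0.1)
  expect_gt(cor(ya, za), 0.3)
  ## collinear variable: undefined with a warning
  expect_warning(r <- partialCorr(2 * x1[1:50] + 3, z[1:50], cbind(x1[1:50])),
                 "undefined")
  expect_true(is.nan(r))
})

test_that("partial correlation equals the recursion formula", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    y <- rnorm(n); z <- rnorm(n); x <- rnorm(n)
    ryz <- cor(y, z); ryx <- cor(y, x); rzx <- cor(z, x)
    oracle <- (ryz - ryx * rzx) / sqrt((1 - ryx^2) * (1 - rzx^2))
    expect_equal(partialCorr(y, z, cbind(x)), oracle, tolerance = 1e-10)
  }
})

test_that("the cross-correlation matrix is consistent and invariant", {
  set.seed(3)
  n <- 30
  G <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("g", 1:3)))
  M <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4)))
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("age", "drug")))
  res <- crossCorrMatrix(G, M, X)
  expect_equal(dim(partialR(res)), c(3L, 4L))
  expect_equal(partialR(res)[2, 3],
               partialCorr(M[, 3], G[, 2], X), tolerance = 1e-12)
  ## 1x1 case reduces to partialCorr
  r11 <- crossCorrMatrix(G[, 1, drop = FALSE], M[, 1, drop = FALSE], X)
  expect_equal(unname(partialR(r11)[1, 1]),
               partialCorr(M[, 1], G[, 1], X), tolerance = 1e-12)
  ## joint permutation of sample order changes nothing
  p <- sample(n)
  res2 <- crossCorrMatrix(G[p, ], M[p, ], X[p, ])
  expect_equal(partialR(res), partialR(res2), tolerance = 1e-12)
})

test_that("null cohorts give centered cross-correlations", {
  coh <- generateCohort(cohortConfig(effectSize = 0, nCorrBlocks = 0L,
                                     nDiscriminativeGenera = 0L,
                                     nDiscriminativePeaks = 0L, seed = 4))
  G <- abundances(coh)[, 1:20]
  M <- peakAreas(coh)[, 1:10]
  res <- crossCorrMatrix(G, M, confounderMatrix(coh))
  expect_lt(mean(abs(partialR(res))), 0.1)
})

test_that("permutation p-values follow the min-p contracts", {
  set.seed(5)
  n <- 40
  G <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("g", 1:4)))
  M <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("m", 1:5)))
  M[, 1] <- G[, 1] * 2 + rnorm(n, 0, 0.2)  # one strong association
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "age"))
  ## B must exceed the entry count for the min-p floor to clear alpha
  res <- pminAdjust(G, M, X, B = 999, seed = 6)
  expect_true(all(adjustedP(res) >= rawP(res) - 1e-12))
  expect_true(all(rawP(res) >= 1 / 1000 - 1e-12))
  ## the planted entry beats every permutation
  expect_equal(rawP(res)["g1", "m1"], 1 / 1000)
  expect_true(highlightMask(res)["g1", "m1"])
  ## adjusted p monotone in raw-p order
  o <- order(as.vector(rawP(res)))
  expect_true(all(diff(as.vector(adjustedP(res))[o]) >= -1e-12))
  ## determinism
  res2 <- pminAdjust(G, M, X, B = 999, seed = 6)
  expect_identical(adjustedP(res), adjustedP(res2))
  ## B too small for alpha warns
  expect_warning(pminAdjust(G, M, X, B = 10, seed = 1, alpha = 0.05),
                 "too small")
})

test_that("Ward bi-clustering recovers planted blocks and degenerate cuts", {
  ## planted r-profiles: two groups of identical rows / columns
  set.seed(20)
  base <- rbind(c(0.8, 0.8, -0.2, -0.2), c(-0.5, -0.5, 0.6, 0.6))
  r <- base[rep(1:2, each = 3), ] + matrix(rnorm(24, 0, 0.01), 6, 4)
  dimnames(r) <- list(paste0("g", 1:6), paste0("m", 1:4))
  cm <- clusterBidirectional(r, kG = 2, kM = 2)
  gc <- genusClusters(cm)
  expect_equal(length(unique(gc[1:3])), 1L)
  expect_equal(length(unique(gc[4:6])), 1L)
  expect_false(gc[1] == gc[4])
  ## duplicated row lands with its twin
  r2 <- rbind(r, g7 = r["g1", ])
  cm2 <- clusterBidirectional(r2, kG = 3, kM = 2)
  expect_equal(unname(genusClusters(cm2)["g7"]),
               unname(genusClusters(cm2)["g1"]))
  ## k = dimension gives singletons
  cmS <- clusterBidirectional(r, kG = 6, kM = 4)
  expect_equal(sort(unname(genusClusters(cmS))), 1:6)
  expect_error(clusterBidirectional(r, kG = 0, kM = 2), "kG")
  expect_error(clusterBidirectional(r, kG = 2, kM = 9), "kM")
  rBad <- r; rBad[1, 1] <- NA
  expect_error(clusterBidirectional(rBad, 2, 2), "finite")
})

test_that("all-singleton aggregation reproduces the full matrix", {
  coh <- smallCohort(seed = 7L)
  G <- abundances(coh)[, 1:8]
  M <- peakAreas(coh)[, 1:6]
  X <- confounderMatrix(coh)
  full <- pminAdjust(G, M, X, B = 50, seed = 8)
  cm <- clusterBidirectional(partialR(full), kG = 8, kM = 6)
  ## restrict the cohort view to the same features
  cohSub <- new("MultiOmicCohort", abundance = G / rowSums(G), peaks = M,
                sampleData = sampleData(coh), truth = list())
  ## singleton centroids equal the (rescaled) features; correlation is
  ## scale-free per feature only for the peak side, so compare against a
  ## matrix computed on the same centroid inputs
  cm <- centroidSimplifiedMatrix(cohSub, cm, X, B = 50, seed = 8)
  simp <- simplifiedResult(cm)
  expect_equal(dim(partialR(simp)), c(8L, 6L))
  ## cluster numbering follows feature order, so entries must match 1:1
  expect_equal(unname(partialR(simp)),
               unname(partialR(pminAdjust(cohSub@abundance, M, X,
                                          B = 50, seed = 8))),
               tolerance = 1e-12)
  ## centroids of singletons equal the features themselves
  expect_equal(unname(cm@genusCentroids), unname(cohSub@abundance),
               tolerance = 1e-15)
})

test_that("centroids ignore the order of features within a cluster", {
  coh <- smallCohort(seed = 9L)
  ab <- abundances(coh)[, 1:6]
  asg <- c(1L, 1L, 2L, 2L, 2L, 1L)
  names(asg) <- colnames(ab)
  c1 <- micromet:::.centroids(ab, asg, "G")
  perm <- c(6, 3, 1, 5, 2, 4)
  c2 <- micromet:::.centroids(ab[, perm], asg[perm], "G")
  expect_equal(c1, c2)
})
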