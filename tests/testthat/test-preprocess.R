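test_that("overall-abundance filter uses a strict mean threshold", {
  ab <- cbind(a = rep(0.05, 10), b = rep(0.01, 10), c = rep(0.94, 10))
  out <- filterGenusAbundance(ab, cutoff = 0.01)
  expect_identical(colnames(out), c("a", "c"))  # 0.01 is not > 0.01
  uniform <- matrix(1 / 130, 20, 130,
                    dimnames = list(NULL, paste0("g", 1:130)))
  expect_error(filterGenusAbundance(uniform), "every genus")
})

test_that("zero-prevalence filter removes only strictly > cutoff", {
  m <- cbind(keep95 = c(rep(0, 95), rep(1, 5)),
             drop96 = c(rep(0, 96), rep(1, 4)),
             dense = rexp(100))
  out <- filterZeroPrevalence(m, cutoff = 0.95)
  expect_identical(colnames(out), c("keep95", "dense"))
  nz <- matrix(rexp(50), 10, 5)
  expect_identical(filterZeroPrevalence(nz), nz)
})

test_that("MSTUS normalization matches its definition", {
  ## all peaks shared: rows sum to 1
  full <- matrix(rexp(30) + 0.1, 5, 6)
  expect_equal(rowSums(mstusNormalize(full)), rep(1, 5))
  ## per-sample scale invariance
  scaled <- full
  scaled[2, ] <- scaled[2, ] * 7
  expect_equal(mstusNormalize(scaled)[2, ], mstusNormalize(full)[2, ])
  ## hand-computed 3x3 with one undetected cell: divisor excludes peak 3
  pk <- rbind(s1 = c(2, 3, 5), s2 = c(4, 1, 0), s3 = c(1, 1, 1))
  colnames(pk) <- c("p1", "p2", "p3")
  out <- mstusNormalize(pk)
  expect_equal(out["s1", ], c(p1 = 2, p2 = 3, p3 = 5) / 5)
  expect_equal(out["s2", ], c(p1 = 4, p2 = 1, p3 = 0) / 5)
  expect_equal(out["s3", ], c(p1 = 1, p2 = 1, p3 = 1) / 2)
  ## a sample with zero total useful signal is an error naming it
  bad <- rbind(c(0, 0, 0), c(1, 2, 1), c(1, 1, 1))
  rownames(bad) <- c("sampleA", "x", "y")
  expect_error(suppressWarnings(mstusNormalize(bad)), "sampleA")
  ## no peak complete across samples: fall back to all peaks with warning
  part <- rbind(c(0, 2, 3), c(1, 0, 2), c(1, 1, 0))
  expect_warning(out2 <- mstusNormalize(part), "falls back")
  expect_equal(rowSums(out2), rep(1, 3))
})

test_that("fold preprocessing trims exactly floor(frac * n) samples", {
  set.seed(1)
  x <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(sprintf("s%03d", 1:100), paste0("f", 1:5)))
  for (frac in c(0, 0.01, 0.05, 0.2, 0.33)) {
    pp <- fitFoldPreprocess(x, outlierFrac = frac, nTrees = 50L, seed = 2L)
    expect_length(pp$removed, floor(frac * 100))
  }
  ## frac = 0 reduces to plain standardization
  pp0 <- fitFoldPreprocess(x, outlierFrac = 0, nTrees = 50L, seed = 2L)
  expect_equal(pp0$center, colMeans(x))
  expect_equal(pp0$scale, apply(x, 2, sd))
})

test_that("the isolation forest isolates a gross outlier", {
  ## oracle: the planted point is the unique nearest-neighbour outlier
  set.seed(3)
  x <- rbind(matrix(rnorm(99 * 2, 0, 0.5), 99, 2), c(10, 10))
  rownames(x) <- sprintf("s%03d", 1:100)
  colnames(x) <- c("u", "v")
  pp <- fitFoldPreprocess(x, outlierFrac = 0.01, nTrees = 100L, seed = 4L)
  expect_identical(pp$removedIds, "s100")
  D <- as.matrix(dist(x)); diag(D) <- Inf
  expect_identical(which.max(apply(D, 1, min)), c(s100 = 100L))
})

test_that("applying a model standardizes and never touches test rows", {
  set.seed(5)
  x <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(sprintf("s%02d", 1:60), paste0("f", 1:4)))
  pp <- fitFoldPreprocess(x, outlierFrac = 0.05, nTrees = 50L, seed = 6L)
  z <- applyFoldPreprocess(pp, x)[pp$keptIds, ]
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4))
  ## a test sample at the training mean maps to zero
  mid <- matrix(pp$center, 1, 4, dimnames = list("t", paste0("f", 1:4)))
  expect_equal(unname(applyFoldPreprocess(pp, mid)[1, ]), rep(0, 4))
  expect_error(applyFoldPreprocess(pp, x[, c(2, 1, 3, 4)]), "mismatch")
})

test_that("constant features get unit scale with a warning", {
  x <- cbind(f1 = rnorm(30), f2 = rep(2, 30))
  rownames(x) <- sprintf("s%02d", 1:30)
  expect_warning(pp <- fitFoldPreprocess(x, outlierFrac = 0, seed = 1L),
                 "constant")
  expect_equal(unname(pp$scale["f2"]), 1)
  z <- applyFoldPreprocess(pp, x)
  expect_equal(unname(z[, "f2"]), rep(0, 30))  # location shift only
})

test_that("fitting ignores anything outside the training fold", {
  set.seed(7)
  x <- matrix(rnorm(50 * 3), 50, 3,
              dimnames = list(sprintf("s%02d", 1:50), paste0("f", 1:3)))
  p1 <- fitFoldPreprocess(x, outlierFrac = 0.1, nTrees = 50L, seed = 8L)
  p2 <- fitFoldPreprocess(x, outlierFrac = 0.1, nTrees = 50L, seed = 8L)
  expect_identical(p1, p2)
})
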