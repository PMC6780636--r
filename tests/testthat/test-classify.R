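test_that("fold plans stratify, partition, and reproduce under a seed", {
  coh <- generateCohort(cohortConfig(seed = 1L))
  md <- sampleData(coh)
  p1 <- buildFoldPlan(md, repeats = 2, outer = 5, inner = 5, seed = 3)
  p2 <- buildFoldPlan(md, repeats = 2, outer = 5, inner = 5, seed = 3)
  expect_identical(p1@plan, p2@plan)
  ids <- rownames(md)
  paps <- ids[md$group == "PAPS"]
  for (r in 1:2) {
    tests <- lapply(1:5, function(k) foldCell(p1, r, k)$test)
    expect_setequal(unlist(tests), ids)                 # partition
    expect_identical(anyDuplicated(unlist(tests)), 0L)
    for (k in 1:5) {
      cell <- foldCell(p1, r, k)
      expect_gte(sum(cell$test %in% paps), 2L)          # 11 PAPS over 5 folds
      expect_length(intersect(cell$train, cell$test), 0L)
      innerTests <- unlist(lapply(cell$inner, `[[`, "test"))
      expect_setequal(innerTests, cell$train)           # inner partition
    }
  }
  expect_error(buildFoldPlan(data.frame(group = factor(rep(c("a", "b"),
    c(3, 20))), row.names = sprintf("s%02d", 1:23)), outer = 5), "a")
})

test_that("balanced two-fold split of ten samples gives two folds of five", {
  md <- data.frame(group = factor(rep(c("x", "y"), each = 5)),
                   row.names = paste0("s", 1:10))
  p <- buildFoldPlan(md, repeats = 1, outer = 2, inner = 2, seed = 1)
  expect_length(foldCell(p, 1, 1)$test, 5L)
  expect_length(foldCell(p, 1, 2)$test, 5L)
})

test_that("pairwise metrics match hand computation and C(k,2) structure", {
  ## perfect prediction
  y <- factor(rep(c("a", "b", "c"), each = 4))
  sc <- diag(3)[as.integer(y), ]
  colnames(sc) <- levels(y)
  ms <- pairwiseMetrics(y, y, sc)
  expect_equal(nrow(pairwiseTable(ms)), 3L)
  expect_equal(unname(weightedMeans(ms)), c(1, 1, 1))
  ## hand-computed confusion: TP=8 FN=2 / TN=5 FP=5
  truth <- factor(rep(c("a", "b"), c(10, 10)))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 5), rep("b", 5))
  sc2 <- cbind(a = ifelse(pred == "a", 0.9, 0.1),
               b = ifelse(pred == "a", 0.1, 0.9))
  ms2 <- pairwiseMetrics(truth, pred, sc2)
  tab <- pairwiseTable(ms2)
  expect_equal(tab$BA, (0.8 + 0.5) / 2)
  expect_equal(tab$F1, 2 * 8 / (2 * 8 + 5 + 2))
  ## five classes produce all 10 pairs
  y5 <- factor(rep(letters[1:5], each = 3))
  sc5 <- matrix(1 / 5, 15, 5, dimnames = list(NULL, letters[1:5]))
  ms5 <- pairwiseMetrics(y5, y5, sc5)
  expect_equal(nrow(pairwiseTable(ms5)), choose(5, 2))
  expect_equal(sum(pairwiseTable(ms5)$weight), 1)
})

test_that("pairwise AUROC equals the Mann-Whitney statistic", {
  set.seed(11)
  for (i in 1:20) {
    nA <- sample(5:15, 1); nB <- sample(5:15, 1)
    truth <- factor(rep(c("a", "b"), c(nA, nB)))
    sa <- runif(nA + nB)
    sc <- cbind(a = sa, b = 1 - sa)
    pred <- ifelse(sa > 0.5, "a", "b")
    ms <- pairwiseMetrics(truth, pred, sc)
    u <- wilcox.test(sa[truth == "a"], sa[truth == "b"],
                     exact = FALSE)$statistic
    expect_equal(pairwiseTable(ms)$AUROC, unname(u) / (nA * nB),
                 tolerance = 1e-12)
  }
})

test_that("constant majority prediction scores BA 0.5 on a balanced pair", {
  truth <- factor(rep(c("a", "b"), each = 10))
  pred <- rep("a", 20)
  sc <- cbind(a = rep(0.6, 20), b = rep(0.4, 20))
  ms <- pairwiseMetrics(truth, pred, sc)
  expect_equal(pairwiseTable(ms)$BA, 0.5)
})

test_that("a pair with an absent class is skipped with renormalization", {
  truth <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "c"))
  pred <- c("a", "b", "b", "b")
  sc <- matrix(1 / 3, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(ms <- pairwiseMetrics(truth, pred, sc), "skipped")
  expect_equal(nrow(pairwiseTable(ms)), 1L)
  expect_equal(sum(pairwiseTable(ms)$weight), 1)
})

test_that("model selection honours restriction and the naive-Bayes tie rule", {
  d <- separableData(n = 40, p = 4, seed = 2)
  plan <- buildFoldPlan(data.frame(group = d$y, row.names = rownames(d$x)),
                        repeats = 1, outer = 2, inner = 3, seed = 5)
  innerCells <- foldCell(plan, 1, 1)$inner
  xtr <- d$x[foldCell(plan, 1, 1)$train, ]
  ytr <- d$y[match(foldCell(plan, 1, 1)$train, rownames(d$x))]
  zoo1 <- structure("rf", nTrees = 30L)
  pick1 <- innerSelectModel(xtr, ytr, innerCells, zoo = zoo1,
                            iforestTrees = 30L, seed = 1)
  expect_identical(pick1$learner, "rf")
  ## perfectly separable: all learners hit 1.0, tie goes to naive Bayes
  pick <- innerSelectModel(xtr, ytr, innerCells, zoo = modelZoo(30L),
                           iforestTrees = 30L, seed = 1)
  expect_identical(pick$learner, "nb")
  expect_equal(pick$fitness, 1)
})

test_that("hill climbing strips noise around a perfect separator", {
  d <- separableData(n = 40, p = 10, seed = 3)
  plan <- buildFoldPlan(data.frame(group = d$y, row.names = rownames(d$x)),
                        repeats = 1, outer = 2, inner = 3, seed = 6)
  cell <- foldCell(plan, 1, 1)
  xtr <- d$x[cell$train, ]
  ytr <- d$y[match(cell$train, rownames(d$x))]
  zoo <- structure("nb", nTrees = 30L)
  kept <- vapply(1:5, function(s) {
    hc <- hillClimbFeatures(xtr, ytr, cell$inner, zoo = zoo,
                            budget = 100L, iforestTrees = 30L, seed = s)
    expect_equal(hc$fitness, 1)
    expect_true("f1" %in% hc$features)
    length(hc$features)
  }, numeric(1))
  ## at least 80% of the 9 noise features dropped (median over seeds)
  expect_lte(median(kept) - 1, 0.2 * 9)
})

test_that("accepted fitness is monotone along the hill-climb trace", {
  coh <- smallCohort(seed = 5L)
  x <- filterGenusAbundance(abundances(coh))
  y <- sampleGroups(coh)
  plan <- buildFoldPlan(sampleData(coh), repeats = 1, outer = 3, inner = 3,
                        seed = 7)
  cell <- foldCell(plan, 1, 1)
  hc <- hillClimbFeatures(x[cell$train, ], y[match(cell$train, rownames(x))],
                          cell$inner, zoo = structure("nb", nTrees = 30L),
                          budget = 10L, iforestTrees = 30L, seed = 8)
  acc <- hc$trace[hc$trace$accepted, ]
  expect_true(all(diff(acc$fitness) >= -1e-12))
  expect_error(hillClimbFeatures(x[cell$train, ],
                                 y[match(cell$train, rownames(x))],
                                 cell$inner, budget = 0L), "budget")
})

test_that("nested CV is deterministic under a fixed seed", {
  coh <- smallCohort(seed = 6L, effectSize = 1.5)
  cfg <- quickRunConfig(seed = 21L)
  r1 <- suppressWarnings(nestedCVEvaluate(coh, cfg))
  r2 <- suppressWarnings(nestedCVEvaluate(coh, cfg))
  expect_identical(weightedMeans(cvMetrics(r1)), weightedMeans(cvMetrics(r2)))
  expect_identical(consensusFeatures(r1), consensusFeatures(r2))
  expect_identical(r1@selection, r2@selection)
  expect_s4_class(cvMetrics(r1), "MetricSet")
  expect_true(all(weightedMeans(cvMetrics(r1)) >= 0 &
                  weightedMeans(cvMetrics(r1)) <= 1))
})

test_that("outer-fold models never see the outer test fold", {
  coh <- smallCohort(seed = 9L, effectSize = 1)
  x <- filterGenusAbundance(abundances(coh))
  y <- sampleGroups(coh)
  plan <- buildFoldPlan(sampleData(coh), repeats = 1, outer = 3, inner = 3,
                        seed = 10)
  cell <- foldCell(plan, 1, 1)
  cfg <- quickRunConfig(seed = 31L)
  res1 <- suppressWarnings(micromet:::.runOuterCell(x, y, cell, cfg, 77L))
  ## replace the outer test rows with pure noise and rerun
  x2 <- x
  set.seed(99)
  x2[cell$test, ] <- matrix(runif(length(cell$test) * ncol(x)),
                            length(cell$test), ncol(x))
  res2 <- suppressWarnings(micromet:::.runOuterCell(x2, y, cell, cfg, 77L))
  expect_identical(res1$features, res2$features)
  expect_identical(res1$learner, res2$learner)
  expect_identical(res1$preprocess$center, res2$preprocess$center)
  expect_identical(res1$preprocess$scale, res2$preprocess$scale)
  expect_identical(res1$preprocess$removedIds, res2$preprocess$removedIds)
  expect_identical(res1$trace, res2$trace)
})
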