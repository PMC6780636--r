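#' Build a stratified repeated nested cross-validation plan
#'
#' Within each repeat, every group's samples are shuffled and dealt
#' round-robin into the outer folds, so each outer test fold holds
#' `floor(n_g/K)` or `ceiling(n_g/K)` members of group g; each outer
#' training set is split the same way into inner folds.
#'
#' @param metadata data.frame with a `group` factor and sample ids as
#'   rownames (e.g. `sampleData(cohort)`).
#' @param repeats,outer,inner plan dimensions (defaults 10 x 5 x 5).
#' @param seed integer seed.
#' @return A [FoldPlan-class].
#' @export
buildFoldPlan <- function(metadata, repeats = 10L, outer = 5L, inner = 5L,
                          seed = 1L) {
  stopifnot(outer >= 2L, inner >= 2L, repeats >= 1L)
  groups <- factor(metadata$group)
  ids <- rownames(metadata)
  sizes <- table(groups)
  small <- names(sizes)[sizes < outer]
  if (length(small))
    stop("group(s) smaller than the outer fold count: ",
         paste(small, collapse = ", "))
  stratSplit <- function(ids, groups, k) {
    fold <- integer(length(ids))
    foldSizes <- integer(k)
    for (g in levels(droplevels(groups))) {
      i <- which(groups == g)
      i <- i[sample.int(length(i))]
      ## deal round-robin starting from the currently smallest folds, so
      ## per-group remainders do not pile up in the same fold
      ord <- sample.int(k)
      ord <- ord[order(foldSizes[ord])]
      f <- rep_len(ord, length(i))
      fold[i] <- f
      foldSizes <- foldSizes + tabulate(f, k)
    }
    lapply(seq_len(k), function(f) ids[fold == f])
  }
  set.seed(as.integer(seed))
  plan <- lapply(seq_len(repeats), function(r) {
    outerTest <- stratSplit(ids, groups, outer)
    lapply(seq_len(outer), function(k) {
      test <- outerTest[[k]]
      train <- setdiff(ids, test)
      gTrain <- groups[match(train, ids)]
      innerTest <- stratSplit(train, gTrain, inner)
      innerCells <- lapply(innerTest, function(it)
        list(train = setdiff(train, it), test = it))
      list(train = train, test = test, inner = innerCells)
    })
  })
  new("FoldPlan", plan = plan, repeats = as.integer(repeats),
      outerFolds = as.integer(outer), innerFolds = as.integer(inner),
      seed = as.integer(seed))
}

#' One-vs-one balanced accuracy, F1 and AUROC
#'
#' For each unordered class pair (a, b) with a lexicographically first, the
#' evaluation set is restricted to samples truly in \{a, b\}: sensitivity is
#' the recall of a, specificity the recall of b, BA their mean; F1 is
#' computed for class a from the restricted confusion counts; AUROC is the
#' rank-based area under the curve of the normalized two-class score
#' `s(a) / (s(a) + s(b))`. Pair weights are proportional to the restricted
#' sample counts; pairs missing a class are skipped with a warning and the
#' weights renormalized.
#'
#' @param truth factor of true labels.
#' @param predicted factor/character of predicted labels.
#' @param scores samples x classes score matrix, rows summing to 1, with
#'   class names as colnames.
#' @return A [MetricSet-class].
#' @export
pairwiseMetrics <- function(truth, predicted, scores) {
  if (!is.factor(truth)) truth <- factor(truth)  # keep declared levels
  predicted <- as.character(predicted)
  lv <- sort(levels(truth))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    sel <- truth %in% pr
    ta <- truth[sel] == a
    if (!any(ta) || all(ta)) return(NULL)  # one class absent
    pa <- predicted[sel]
    sens <- mean(pa[ta] == a)
    spec <- mean(pa[!ta] == b)
    tp <- sum(ta & pa == a); fn <- sum(ta & pa != a)
    fp <- sum(!ta & pa == a)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    sa <- scores[sel, a]; sb <- scores[sel, b]
    tot <- sa + sb
    s <- ifelse(tot > 0, sa / tot, 0.5)
    auc <- .rankAUC(s, ta)
    data.frame(classA = a, classB = b, n = sum(sel), BA = (sens + spec) / 2,
               F1 = f1, AUROC = auc)
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped))
    warning(sum(skipped), " class pair(s) with an absent class skipped; ",
            "weights renormalized")
  tab <- do.call(rbind, rows[!skipped])
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no evaluable class pair")
  tab$weight <- tab$n / sum(tab$n)
  tab <- tab[, c("classA", "classB", "n", "weight", "BA", "F1", "AUROC")]
  w <- c(BA = sum(tab$weight * tab$BA),
         F1 = sum(tab$weight * tab$F1),
         AUROC = sum(tab$weight * tab$AUROC))
  new("MetricSet", pairwise = tab, weighted = w,
      repeatSD = c(BA = NA_real_, F1 = NA_real_, AUROC = NA_real_),
      perRepeat = data.frame())
}

## Mann-Whitney / rank formulation of the AUC with tie correction.
.rankAUC <- function(score, isPositive) {
  nPos <- sum(isPositive); nNeg <- sum(!isPositive)
  r <- rank(score)
  (sum(r[isPositive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## ---- inner-CV machinery ---------------------------------------------------

## Precompute, for one outer cell, the standardized inner-fold matrices on
## the full post-filter feature set. Candidate feature subsets then index
## columns: standardization is per-feature so this is exact, and the
## isolation-forest outlier set is held fixed across subsets.
.innerCache <- function(x, y, innerCells, outlierFrac, nTrees, seed) {
  yOf <- function(ids) y[match(ids, rownames(x))]
  lapply(seq_along(innerCells), function(j) {
    cell <- innerCells[[j]]
    xtr <- x[cell$train, , drop = FALSE]
    pp <- suppressWarnings(
      fitFoldPreprocess(xtr, outlierFrac = outlierFrac, nTrees = nTrees,
                        seed = seed + j))
    kept <- pp$keptIds
    list(xtr = applyFoldPreprocess(pp, xtr)[kept, , drop = FALSE],
         ytr = yOf(kept),
         xte = applyFoldPreprocess(pp, x[cell$test, , drop = FALSE]),
         yte = yOf(cell$test))
  })
}

## Fitness of (subset, learner): weighted pairwise BA of the pooled
## inner-fold predictions.
.innerFitness <- function(cache, subset, kind, nTrees, seed, allLevels) {
  preds <- character(0); truths <- factor(character(0), levels = allLevels)
  scores <- NULL
  for (cell in cache) {
    fit <- .fitLearner(kind, cell$xtr[, subset, drop = FALSE], cell$ytr,
                       nTrees = nTrees, seed = seed)
    pr <- .predictLearner(fit, cell$xte[, subset, drop = FALSE])
    full <- matrix(0, nrow(pr), length(allLevels),
                   dimnames = list(NULL, allLevels))
    full[, colnames(pr)] <- pr
    scores <- rbind(scores, full)
    preds <- c(preds, colnames(pr)[max.col(pr, ties.method = "first")])
    truths <- c(truths, cell$yte)
  }
  ms <- suppressWarnings(pairwiseMetrics(truths, preds, scores))
  unname(ms@weighted["BA"])
}

#' Inner-CV model selection over the zoo
#'
#' Evaluates each candidate learner of the zoo on the inner folds of one
#' outer training set (fold-wise standardization and outlier trimming
#' already applied) with the given feature subset, and returns the learner
#' with the highest inner fitness (weighted pairwise BA of the pooled
#' inner-fold predictions). Ties break by zoo order, naive Bayes first.
#'
#' @param x outer-training samples x features matrix (raw scale).
#' @param y factor of outer-training labels.
#' @param innerCells list of `list(train, test)` sample-id cells.
#' @param features character vector, the candidate feature subset.
#' @param zoo from [modelZoo()].
#' @param outlierFrac,iforestTrees preprocessing parameters.
#' @param seed integer seed.
#' @return list with `learner` (name), `fitness`, and `all` (named fitness
#'   of every candidate).
#' @export
innerSelectModel <- function(x, y, innerCells, features = colnames(x),
                             zoo = modelZoo(), outlierFrac = 0.05,
                             iforestTrees = 500L, seed = 1L) {
  stopifnot(length(features) >= 1L)
  cache <- .innerCache(x, y, innerCells, outlierFrac, iforestTrees, seed)
  .selectFromCache(cache, features, zoo, seed, levels(factor(y)))
}

.selectFromCache <- function(cache, features, zoo, seed, allLevels) {
  nTrees <- attr(zoo, "nTrees")
  fits <- vapply(zoo, function(kind)
    .innerFitness(cache, features, kind, nTrees, seed, allLevels),
    numeric(1))
  best <- which.max(fits)  # which.max takes the first maximum: zoo order
  list(learner = zoo[[best]], fitness = unname(fits[best]), all = fits)
}

#' Stochastic hill-climbing feature selection
#'
#' Local search over feature-inclusion bit vectors, scored by the inner-CV
#' weighted pairwise balanced accuracy of the currently selected learner.
#' Starts from the full feature set; each iteration flips one uniformly
#' random feature and accepts the move if fitness strictly improves, or is
#' equal with a smaller subset. The search stops after `budget` consecutive
#' non-acceptances. The learner is re-selected from the zoo every
#' `relearnEvery` accepted moves.
#'
#' @inheritParams innerSelectModel
#' @param budget consecutive non-improving iterations before stopping
#'   (default 200).
#' @param maxIters hard cap on total iterations (accepted or not), so the
#'   search has a predictable worst-case cost; default `10 * budget`.
#' @param relearnEvery accepted moves between learner re-selections.
#' @return list with `features` (selected subset), `learner`, `fitness`,
#'   and `trace` (data.frame: iteration, flipped feature, accepted flag,
#'   fitness, subset size, learner).
#' @export
hillClimbFeatures <- function(x, y, innerCells, zoo = modelZoo(),
                              budget = 200L, maxIters = 10L * budget,
                              relearnEvery = 25L,
                              outlierFrac = 0.05, iforestTrees = 500L,
                              seed = 1L) {
  if (budget < 1L) stop("budget must be >= 1")
  if (ncol(x) < 2L) stop("need at least 2 features to search over")
  cache <- .innerCache(x, y, innerCells, outlierFrac, iforestTrees, seed)
  allLevels <- levels(factor(y))
  feats <- colnames(x)
  set.seed(as.integer(seed))
  sel <- rep(TRUE, length(feats))
  pick <- .selectFromCache(cache, feats, zoo, seed, allLevels)
  learner <- pick$learner
  fcur <- pick$fitness
  trace <- list(list(iteration = 0L, feature = NA_character_,
                     accepted = TRUE, fitness = fcur,
                     size = sum(sel), learner = learner))
  misses <- 0L; iter <- 0L; accepts <- 0L
  nTrees <- attr(zoo, "nTrees")
  while (misses < budget && iter < maxIters) {
    iter <- iter + 1L
    j <- sample.int(length(feats), 1L)
    cand <- sel
    cand[j] <- !cand[j]
    if (!any(cand)) { misses <- misses + 1L; next }
    f <- .innerFitness(cache, feats[cand], learner, nTrees, seed, allLevels)
    better <- f > fcur + 1e-12
    equalSmaller <- abs(f - fcur) <= 1e-12 && sum(cand) < sum(sel)
    accepted <- better || equalSmaller
    if (accepted) {
      sel <- cand; fcur <- f
      misses <- 0L
      accepts <- accepts + 1L
      if (accepts %% relearnEvery == 0L) {
        pick <- .selectFromCache(cache, feats[sel], zoo, seed, allLevels)
        learner <- pick$learner
        fcur <- pick$fitness
      }
    } else misses <- misses + 1L
    trace[[length(trace) + 1L]] <-
      list(iteration = iter, feature = feats[j], accepted = accepted,
           fitness = if (accepted) fcur else f, size = sum(cand),
           learner = learner)
  }
  trace <- do.call(rbind, lapply(trace, as.data.frame))
  list(features = feats[sel], learner = learner, fitness = fcur,
       trace = trace)
}

## Run one outer cell end to end: feature + model selection on the outer
## training set only, final refit, prediction of the untouched test fold.
## Deterministic in (train data, test ids, cellSeed).
.runOuterCell <- function(x, y, cell, config, cellSeed) {
  xtr <- x[cell$train, , drop = FALSE]
  ytr <- droplevels(y[match(cell$train, rownames(x))])
  ## fold-local zero-prevalence filter
  xtr <- filterZeroPrevalence(xtr, config$zeroPrevalenceCutoff)
  feats <- colnames(xtr)
  zoo <- config$zoo
  hc <- hillClimbFeatures(xtr, ytr, cell$inner, zoo = zoo,
                          budget = config$hillClimbBudget,
                          maxIters = config$hillClimbMaxIters %||%
                            (10L * config$hillClimbBudget),
                          relearnEvery = config$relearnEvery,
                          outlierFrac = config$outlierFrac,
                          iforestTrees = config$isolationTrees,
                          seed = cellSeed)
  ## final model: preprocess the full outer-training set, refit, predict
  pp <- suppressWarnings(
    fitFoldPreprocess(xtr, outlierFrac = config$outlierFrac,
                      nTrees = config$isolationTrees, seed = cellSeed))
  xtrS <- applyFoldPreprocess(pp, xtr)[pp$keptIds, , drop = FALSE]
  fit <- .fitLearner(hc$learner, xtrS[, hc$features, drop = FALSE],
                     ytr[match(pp$keptIds, cell$train)],
                     nTrees = attr(zoo, "nTrees"), seed = cellSeed)
  xte <- x[cell$test, feats, drop = FALSE]
  xteS <- applyFoldPreprocess(pp, xte)
  pr <- .predictLearner(fit, xteS[, hc$features, drop = FALSE])
  allLevels <- levels(y)
  scores <- matrix(0, nrow(pr), length(allLevels),
                   dimnames = list(cell$test, allLevels))
  scores[, colnames(pr)] <- pr
  list(features = hc$features, learner = hc$learner,
       innerFitness = hc$fitness, trace = hc$trace,
       preprocess = pp, scores = scores,
       predicted = colnames(pr)[max.col(pr, ties.method = "first")],
       featureUniverse = feats)
}

#' Repeated nested cross-validation of a cohort table
#'
#' The full evaluation engine: for every repeat x outer fold, the outer
#' training set alone undergoes fold-local filtering, standardization and
#' outlier trimming, stochastic hill-climbing feature selection and
#' inner-CV model selection; the selected model is refit on the outer
#' training set and scored on the untouched outer test fold. Per-repeat
#' one-vs-one metrics are pooled over the outer folds; the headline numbers
#' are their mean +/- SD across repeats. The consensus subset collects
#' features selected in more than half of the outer models.
#'
#' @param cohort a [MultiOmicCohort-class].
#' @param config a [runConfig()] list; `config$table` chooses `"abundance"`
#'   (genus pipeline: global mean-abundance > 1\% filter) or `"peaks"`
#'   (metabolome pipeline: global MSTUS normalization).
#' @return A [NestedCVResult-class].
#' @export
nestedCVEvaluate <- function(cohort, config = runConfig()) {
  stopifnot(is(cohort, "MultiOmicCohort"))
  y <- sampleGroups(cohort)
  x <- switch(config$table,
    abundance = filterGenusAbundance(abundances(cohort),
                                     config$overallAbundanceCutoff),
    peaks = mstusNormalize(peakAreas(cohort)),
    stop("config$table must be 'abundance' or 'peaks'"))
  plan <- buildFoldPlan(sampleData(cohort), repeats = config$repeats,
                        outer = config$folds, inner = config$innerFolds,
                        seed = config$seed)
  allFeats <- colnames(x)
  cells <- list(); traces <- list(); selRows <- list()
  perRepeat <- list(); pairTabs <- list()
  idx <- 0L
  for (r in seq_len(plan@repeats)) {
    repScores <- NULL; repPred <- character(0)
    repTruth <- factor(character(0), levels = levels(y))
    for (k in seq_len(plan@outerFolds)) {
      idx <- idx + 1L
      cell <- foldCell(plan, r, k)
      cellSeed <- (config$seed + 7919L * r + 104729L * k) %% 2147483647L
      res <- .runOuterCell(x, y, cell, config, cellSeed)
      repScores <- rbind(repScores, res$scores)
      repPred <- c(repPred, res$predicted)
      repTruth <- c(repTruth, y[match(cell$test, rownames(x))])
      cells[[idx]] <- data.frame(
        rep = r, fold = k, learner = res$learner,
        nFeatures = length(res$features), innerFitness = res$innerFitness)
      traces[[idx]] <- res$trace
      selRows[[idx]] <- allFeats %in% res$features
    }
    ms <- suppressWarnings(pairwiseMetrics(repTruth, repPred, repScores))
    perRepeat[[r]] <- data.frame(rep = r, t(ms@weighted))
    pairTabs[[r]] <- ms@pairwise
  }
  perRepeat <- do.call(rbind, perRepeat)
  weighted <- colMeans(perRepeat[, c("BA", "F1", "AUROC")])
  repeatSD <- apply(perRepeat[, c("BA", "F1", "AUROC")], 2L, stats::sd)
  ## pair-level table averaged across repeats (recomputed on pooled data of
  ## the final repeat's structure): report mean pairwise metrics
  selection <- do.call(rbind, selRows)
  colnames(selection) <- allFeats
  consensus <- allFeats[colMeans(selection) > 0.5]
  metrics <- new("MetricSet",
                 pairwise = .meanPairwise(pairTabs),
                 weighted = weighted, repeatSD = repeatSD,
                 perRepeat = perRepeat)
  new("NestedCVResult", metrics = metrics, consensus = consensus,
      selection = selection, cells = do.call(rbind, cells),
      traces = traces, features = allFeats)
}

## average the per-repeat pairwise tables over repeats, by class pair
.meanPairwise <- function(pairTabs) {
  all <- do.call(rbind, pairTabs)
  key <- interaction(all$classA, all$classB, drop = TRUE)
  agg <- lapply(split(all, key), function(d)
    data.frame(classA = d$classA[1L], classB = d$classB[1L],
               n = mean(d$n), weight = mean(d$weight),
               BA = mean(d$BA), F1 = mean(d$F1), AUROC = mean(d$AUROC)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$classA, out$classB), ]
}
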