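## Learner registry backing the model zoo. Every learner takes a numeric
## matrix + factor response and emits per-class probability scores, as the
## soft-voting ensemble and the pairwise AUROC require.

#' The candidate model zoo
#'
#' The five fixed candidates of the model-selection phase, in tie-break
#' order: naive Bayes, adaptive boosting (SAMME with decision stumps),
#' random forest, extremely randomized trees, and a soft-voting ensemble of
#' the previous four.
#'
#' @param nTrees trees per forest and boosting rounds (default 500).
#' @return Character vector of learner names, with `nTrees` attached.
#' @export
modelZoo <- function(nTrees = 500L) {
  structure(c("nb", "adaboost", "rf", "extratrees", "voting"),
            nTrees = as.integer(nTrees))
}

.fitOne <- function(kind, x, y, nTrees, seed) {
  switch(kind,
    nb = e1071::naiveBayes(x, y),
    adaboost = .sammeFit(x, y, nRounds = nTrees),
    rf = ranger::ranger(x = x, y = y, num.trees = nTrees,
                        probability = TRUE, num.threads = 1L, seed = seed),
    extratrees = ranger::ranger(x = x, y = y, num.trees = nTrees,
                                probability = TRUE, splitrule = "extratrees",
                                num.random.splits = 1L, replace = FALSE,
                                sample.fraction = 1, num.threads = 1L,
                                seed = seed),
    stop("unknown learner: ", kind))
}

.predictOne <- function(kind, fit, x, levels) {
  pr <- switch(kind,
    nb = predict(fit, x, type = "raw"),
    adaboost = .sammePredict(fit, x),
    rf = predict(fit, data = x, num.threads = 1L)$predictions,
    extratrees = predict(fit, data = x, num.threads = 1L)$predictions)
  pr <- pr[, levels, drop = FALSE]
  pr[!is.finite(pr)] <- 0
  rs <- rowSums(pr)
  bad <- rs <= 0
  if (any(bad)) pr[bad, ] <- 1 / length(levels)
  pr / pmax(rowSums(pr), .Machine$double.eps)
}

#' @keywords internal
.fitLearner <- function(kind, x, y, nTrees = 500L, seed = 1L) {
  y <- droplevels(y)
  if (kind == "voting") {
    members <- c("nb", "adaboost", "rf", "extratrees")
    fits <- lapply(members, function(k)
      .fitOne(k, x, y, nTrees, seed))
    names(fits) <- members
    structure(list(fits = fits, levels = levels(y)), class = "votingFit",
              kind = "voting")
  } else {
    structure(list(fit = .fitOne(kind, x, y, nTrees, seed),
                   levels = levels(y)), kind = kind)
  }
}

#' @keywords internal
.predictLearner <- function(model, x) {
  kind <- attr(model, "kind")
  lv <- model$levels
  if (kind == "voting") {
    prs <- lapply(names(model$fits), function(k)
      .predictOne(k, model$fits[[k]], x, lv))
    pr <- Reduce(`+`, prs) / length(prs)
  } else {
    pr <- .predictOne(kind, model$fit, x, lv)
  }
  pr
}

## --- SAMME multiclass AdaBoost with decision stumps -----------------------

.sammeFit <- function(x, y, nRounds = 500L) {
  x <- as.matrix(x)
  n <- nrow(x); K <- nlevels(y)
  yi <- as.integer(y)
  ord <- apply(x, 2L, order) - 1L  # 0-based sort orders, fixed across rounds
  storage.mode(ord) <- "integer"
  w <- rep(1 / n, n)
  stumps <- vector("list", nRounds)
  alphas <- numeric(nRounds)
  m <- 0L
  for (r in seq_len(nRounds)) {
    st <- .stumpFit(x, yi - 1L, w, K, ord)
    pred <- .stumpPredictIdx(st, x)
    miss <- pred != yi
    err <- sum(w[miss])
    if (err >= 1 - 1 / K) break        # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    m <- m + 1L
    stumps[[m]] <- st
    alphas[m] <- alpha
    if (err <= 1e-10) break            # perfect stump: nothing left to boost
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(stumps = stumps[seq_len(m)], alphas = alphas[seq_len(m)],
       levels = levels(y), K = K)
}

.stumpPredictIdx <- function(st, x) {
  if (st$feature == 0L) return(rep.int(st$leftClass, nrow(x)))
  ifelse(x[, st$feature] < st$threshold, st$leftClass, st$rightClass)
}

.sammePredict <- function(fit, x) {
  x <- as.matrix(x)
  K <- fit$K
  score <- matrix(0, nrow(x), K, dimnames = list(NULL, fit$levels))
  if (length(fit$stumps) == 0L) return(matrix(1 / K, nrow(x), K,
                                              dimnames = list(NULL, fit$levels)))
  for (m in seq_along(fit$stumps)) {
    pred <- .stumpPredictIdx(fit$stumps[[m]], x)
    score[cbind(seq_len(nrow(x)), pred)] <-
      score[cbind(seq_len(nrow(x)), pred)] + fit$alphas[m]
  }
  score / pmax(rowSums(score), .Machine$double.eps)
}
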