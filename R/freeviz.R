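#' Average silhouette of a labelled embedding
#'
#' Standard silhouette with Euclidean distance: for sample i, `a(i)` is the
#' mean distance to its own class, `b(i)` the smallest mean distance to
#' another class, and `s(i) = (b - a) / max(a, b)`, averaged over samples.
#' Samples in singleton classes get s = 0 by the usual convention; if every
#' class is a singleton the silhouette is undefined and an error is raised.
#' If all samples coincide the score is 0 by convention.
#'
#' @param embedding samples x d numeric matrix.
#' @param labels class labels (>= 2 classes).
#' @return Average silhouette in \[-1, 1\].
#' @export
avgSilhouette <- function(embedding, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need >= 2 classes")
  if (all(table(labels) == 1L))
    stop("silhouette undefined: every class has a single sample")
  D <- as.matrix(stats::dist(embedding))
  if (all(D == 0)) return(0)
  n <- nrow(D)
  lv <- levels(labels)
  ## mean distance from each sample to each class
  md <- vapply(lv, function(g) {
    cols <- labels == g
    rowSums(D[, cols, drop = FALSE]) / sum(cols)
  }, numeric(n))
  sizes <- table(labels)[lv]
  own <- match(labels, lv)
  s <- vapply(seq_len(n), function(i) {
    ni <- sizes[own[i]]
    if (ni == 1L) return(0)
    a <- md[i, own[i]] * ni / (ni - 1)  # exclude self (distance 0)
    b <- min(md[i, -own[i]])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' FreeViz-style radial projection
#'
#' Linear 2-D projection `E = Xs %*% A` of standardized features, where the
#' per-feature anchors A are optimized by class-dependent forces:
#' same-class sample pairs attract with force proportional to their
#' distance, different-class pairs repel with force proportional to
#' 1/distance (capped near zero distance). Point forces are back-projected
#' onto the anchors (`t(X) %*% F`), and after every step the anchors are
#' rescaled so the largest norm is 1. Runs a fixed number of iterations and
#' records the average silhouette of the embedding at each step.
#'
#' @param table samples x features matrix, already standardized.
#' @param labels class labels (>= 2 classes; classes with a single sample
#'   are excluded from force computation with a warning).
#' @param iters number of gradient steps.
#' @param step learning rate (0 leaves the anchors at initialization).
#' @param seed integer seed for the anchor initialization.
#' @return A [ProjectionModel-class].
#' @export
freevizFit <- function(table, labels, iters = 200L, step = 0.05, seed = 1L) {
  X <- as.matrix(table)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need >= 2 classes")
  n <- nrow(X); p <- ncol(X)
  singleton <- names(which(table(labels) == 1L))
  active <- !(labels %in% singleton)
  if (length(singleton))
    warning("class(es) with a single sample excluded from forces: ",
            paste(singleton, collapse = ", "))
  set.seed(as.integer(seed))
  ## anchors initialized on the unit circle in seeded random order
  ang <- 2 * pi * seq_len(p) / p
  A <- cbind(cos(ang), sin(ang))[sample.int(p), , drop = FALSE]
  rownames(A) <- colnames(X)
  same <- outer(labels[active], labels[active], "==")
  Xa <- X[active, , drop = FALSE]
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    E <- X %*% A
    if (step != 0) {
      Ea <- E[active, , drop = FALSE]
      dx <- outer(Ea[, 1L], Ea[, 1L], "-")
      dy <- outer(Ea[, 2L], Ea[, 2L], "-")
      d <- sqrt(dx^2 + dy^2)
      d <- pmax(d, 1e-3)                       # repulsion cap
      ## force magnitude along (i - j): attraction -d, repulsion +1/d
      coef <- ifelse(same, -1, 1 / d^2)        # x unit vector -> /d
      diag(coef) <- 0
      Fx <- rowSums(coef * dx)
      Fy <- rowSums(coef * dy)
      G <- crossprod(Xa, cbind(Fx, Fy)) / sum(active)
      A <- A + step * G
      A <- A / max(sqrt(rowSums(A^2)), .Machine$double.eps)
      E <- X %*% A
    }
    trace[it] <- avgSilhouette(E, labels)
  }
  E <- X %*% A
  rownames(E) <- rownames(X)
  ellipses <- lapply(levels(labels), function(g) {
    i <- labels == g
    list(center = colMeans(E[i, , drop = FALSE]),
         cov = if (sum(i) > 1L) stats::cov(E[i, , drop = FALSE])
               else matrix(0, 2, 2))
  })
  names(ellipses) <- levels(labels)
  new("ProjectionModel", anchors = A, embedding = E,
      silhouette = avgSilhouette(E, labels),
      trace = trace, classEllipses = ellipses, seed = as.integer(seed))
}
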