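## Demographics used by the generator: per-group age mean/SD and current
## treatment rates mirroring the clinical table of the emulated study design.
.groupDemographics <- data.frame(
  group = c("HC", "SLE", "SjS", "PAPS", "UCTD"),
  ageMean = c(52.47, 47.70, 65.91, 40.36, 52.23),
  ageSD = c(9.96, 16.55, 12.72, 6.17, 12.01),
  hcq = c(0, 0.704, 0.391, 0.727, 0.500),
  prednisone = c(0, 0.259, 0.130, 0.091, 0.346),
  immunosuppressant = c(0, 0.370, 0.087, 0, 0.115),
  stringsAsFactors = FALSE
)

#' Create a synthetic-cohort configuration
#'
#' Defaults emulate the study design the pipeline targets: 114 subjects in
#' five groups (HC 27, SLE 27, SjS 23, PAPS 11, UCTD 26), 130 bacterial
#' genera and 254 metabolite peaks.
#'
#' @param groupSizes named vector of samples per group. Groups other than
#'   the five defaults get HC-like demographics.
#' @param nGenera,nPeaks table dimensions.
#' @param nDiscriminativeGenera,nDiscriminativePeaks number of features
#'   carrying planted group effects.
#' @param effectSize magnitude of the planted log-scale group shifts, in
#'   units of the residual log SD (1).
#' @param nCorrBlocks number of latent genus-metabolite correlation blocks
#'   (5 genera + 6 peaks each).
#' @param blockCorr target raw-scale within-block genus-peak correlation.
#' @param confounderStrength SD of the per-feature age/drug coefficients on
#'   the log scale (0 disables confounding).
#' @param zeroInflation mean probability that a genus is structurally
#'   absent from a sample.
#' @param seed integer RNG seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(effectSize = 1, seed = 1)
#' @export
cohortConfig <- function(groupSizes = c(HC = 27L, SLE = 27L, SjS = 23L,
                                        PAPS = 11L, UCTD = 26L),
                         nGenera = 130L, nPeaks = 254L,
                         nDiscriminativeGenera = 10L,
                         nDiscriminativePeaks = 15L,
                         effectSize = 1,
                         nCorrBlocks = 2L, blockCorr = 0.6,
                         confounderStrength = 0.3,
                         zeroInflation = 0.2,
                         seed = 1L) {
  gs <- as.integer(groupSizes)
  names(gs) <- names(groupSizes)
  new("CohortConfig",
      groupSizes = gs,
      nGenera = as.integer(nGenera), nPeaks = as.integer(nPeaks),
      nDiscriminativeGenera = as.integer(nDiscriminativeGenera),
      nDiscriminativePeaks = as.integer(nDiscriminativePeaks),
      effectSize = as.numeric(effectSize),
      nCorrBlocks = as.integer(nCorrBlocks),
      blockCorr = as.numeric(blockCorr),
      confounderStrength = as.numeric(confounderStrength),
      zeroInflation = as.numeric(zeroInflation),
      seed = as.integer(seed))
}

## Latent-factor loading on the log scale chosen so that two log-normal
## features sharing the factor have raw-scale Pearson correlation ~ rho:
## corr = (e^{lambda^2} - 1) / (e^{lambda^2 + s^2} - 1) with residual log
## variance s^2, giving lambda^2 = log((1 - rho) / (1 - rho e^{s^2})).
.blockLoading <- function(rho, s2) {
  rho <- abs(rho)
  if (rho == 0) return(0)
  stopifnot(rho * exp(s2) < 1)
  sqrt(log((1 - rho) / (1 - rho * exp(s2))))
}

.blockResidualVar <- function(rho) {
  if (abs(rho) == 0) return(1)
  min(0.25, 0.45 * log(1 / abs(rho)))
}

#' Generate a synthetic paired microbiome-metabolome cohort
#'
#' Draws per-sample metadata (group, age, treatment flags), zero-inflated
#' log-normal genus intensities closed to relative abundances, and
#' log-normal metabolite peak areas. Planted discriminative features receive
#' group-specific log-scale mean shifts; latent per-sample factors induce
#' genus-metabolite correlation blocks; age and drug flags contribute to
#' every feature with random coefficients of SD `confounderStrength`. The
#' truth ledger records all planted structure.
#'
#' @param config a [CohortConfig-class] from [cohortConfig()].
#' @return A [MultiOmicCohort-class] whose `plantedTruth()` lists the
#'   discriminative genera/peaks, the per-group log-scale shifts, and the
#'   feature membership of every correlation block.
#' @details The same seed yields bit-identical cohorts. Group sizes must sum
#'   to at least 10 (below that, cross-validation downstream is infeasible)
#'   and the correlation blocks (5 genera + 6 peaks each) must fit into the
#'   requested table dimensions.
#' @examples
#' coh <- generateCohort(cohortConfig(seed = 7))
#' coh
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  n <- sum(config@groupSizes)
  if (n < 10L)
    stop("group sizes sum to ", n, " (< 10): cross-validation infeasible")
  bG <- 5L; bM <- 6L  # features per correlation block
  if (config@nCorrBlocks * bG + config@nDiscriminativeGenera > config@nGenera)
    stop("correlation blocks and discriminative genera exceed nGenera")
  if (config@nCorrBlocks * bM + config@nDiscriminativePeaks > config@nPeaks)
    stop("correlation blocks and discriminative peaks exceed nPeaks")

  set.seed(config@seed)
  groups <- rep(names(config@groupSizes), config@groupSizes)
  ids <- sprintf("S%03d", seq_len(n))

  ## metadata: ages and treatment flags per group
  demo <- .groupDemographics
  age <- numeric(n); hcq <- integer(n); pred <- integer(n); imm <- integer(n)
  for (g in unique(groups)) {
    i <- which(groups == g)
    d <- demo[match(g, demo$group), ]
    if (is.na(d$group)) d <- demo[1L, ]  # unknown group: HC-like
    age[i] <- round(pmax(18, stats::rnorm(length(i), d$ageMean, d$ageSD)), 1)
    hcq[i] <- stats::rbinom(length(i), 1L, d$hcq)
    pred[i] <- stats::rbinom(length(i), 1L, d$prednisone)
    imm[i] <- stats::rbinom(length(i), 1L, d$immunosuppressant)
  }
  md <- data.frame(group = factor(groups), age = age, hcq = hcq,
                   prednisone_gt5 = pred, immunosuppressant = imm,
                   row.names = ids)
  covar <- cbind((age - 50) / 15, hcq, pred, imm)

  gNames <- sprintf("genus_%03d", seq_len(config@nGenera))
  pNames <- sprintf("peak_%03d", seq_len(config@nPeaks))
  grpLevels <- levels(md$group)
  nG <- config@nGenera; nP <- config@nPeaks

  ## partition features: planted discriminative, block members, background
  discG <- if (config@nDiscriminativeGenera > 0L)
    gNames[seq_len(config@nDiscriminativeGenera)] else character()
  discP <- if (config@nDiscriminativePeaks > 0L)
    pNames[seq_len(config@nDiscriminativePeaks)] else character()
  blocks <- list()
  if (config@nCorrBlocks > 0L) {
    for (k in seq_len(config@nCorrBlocks)) {
      gIdx <- config@nDiscriminativeGenera + (k - 1L) * bG + seq_len(bG)
      mIdx <- config@nDiscriminativePeaks + (k - 1L) * bM + seq_len(bM)
      blocks[[k]] <- list(genera = gNames[gIdx], peaks = pNames[mIdx])
    }
  }

  ## group-effect patterns: a permuted graded contrast per planted feature,
  ## so each pair of groups is separated by 0.5-2 x effectSize log-SD units
  pattern <- c(-1, -0.5, 0, 0.5, 1)
  mkShift <- function(nFeat) {
    sh <- matrix(0, nFeat, length(grpLevels),
                 dimnames = list(NULL, grpLevels))
    for (f in seq_len(nFeat))
      sh[f, ] <- config@effectSize *
        sample(rep_len(pattern, length(grpLevels)))
    sh
  }
  shiftG <- mkShift(length(discG))
  shiftP <- mkShift(length(discP))

  ## genus zero-inflation: most genera common, ~8% rare (mostly absent) so
  ## the zero-prevalence filter has something to remove; planted genera and
  ## block members stay prevalent
  zProb <- stats::rbeta(nG, 2, 2 * (1 - config@zeroInflation) /
                              max(config@zeroInflation, 1e-6))
  rare <- stats::runif(nG) < 0.08
  zProb[rare] <- stats::runif(sum(rare), 0.92, 0.995)
  special <- c(match(discG, gNames), match(unlist(lapply(blocks, `[[`, "genera")), gNames))
  zProb[special] <- pmin(zProb[special], 0.1)
  if (config@zeroInflation == 0) zProb[] <- 0

  ## latent block factors
  u <- matrix(stats::rnorm(n * max(config@nCorrBlocks, 1L)), n)
  s2 <- .blockResidualVar(config@blockCorr)
  lam <- .blockLoading(config@blockCorr, s2)

  grpIdx <- as.integer(md$group)

  buildLog <- function(nFeat, names, baseMean, baseSD, disc, shift,
                       blockKey, boost = integer()) {
    mu <- stats::rnorm(nFeat, baseMean, baseSD)
    ## features carrying planted structure are seeded among the abundant
    ## genera, so the canonical >1% mean-abundance filter cannot silently
    ## remove the signal the generator promises
    if (length(boost)) mu[boost] <- stats::rnorm(length(boost), 1.8, 0.3)
    L <- matrix(rep(mu, each = n), n, nFeat, dimnames = list(ids, names))
    eps <- matrix(stats::rnorm(n * nFeat), n, nFeat)
    sdVec <- rep(1, nFeat)
    ## confounder contributions
    if (config@confounderStrength > 0) {
      beta <- matrix(stats::rnorm(nFeat * 4, 0, config@confounderStrength),
                     4, nFeat)
      L <- L + covar %*% beta
    }
    ## planted group shifts
    if (length(disc))
      L[, disc] <- L[, disc] + t(shift)[grpIdx, , drop = FALSE]
    ## correlation blocks
    ## closure of the abundance table adds log-total noise to every genus;
    ## the genus-side loading is inflated to compensate so the *observed*
    ## genus-peak correlation matches blockCorr
    load <- if (blockKey == "peaks")
      sign(config@blockCorr + (config@blockCorr == 0)) * lam
    else 1.6 * lam
    for (k in seq_along(blocks)) {
      feats <- blocks[[k]][[blockKey]]
      L[, feats] <- L[, feats] + load * u[, k]
      sdVec[match(feats, names)] <- sqrt(s2)
    }
    L + eps * rep(sdVec, each = n)
  }

  logG <- buildLog(nG, gNames, 0, 1.2, discG, shiftG, "genera",
                   boost = special)
  logP <- buildLog(nP, pNames, 2, 1.0, discP, shiftP, "peaks")

  ## genus intensities: structural zeros then closure to relative abundances
  present <- matrix(stats::runif(n * nG), n, nG) >= rep(zProb, each = n)
  ## guard: every sample keeps at least one genus
  emptyRows <- rowSums(present) == 0L
  present[emptyRows, 1L] <- TRUE
  intens <- exp(logG) * present
  abundance <- intens / rowSums(intens)

  ## peaks: mild detection dropout on a quarter of the peaks, so the MSTUS
  ## "useful" (complete) peak set is a proper subset
  peaks <- exp(logP)
  sporadic <- stats::runif(nP) < 0.25
  drop <- matrix(stats::runif(n * nP), n, nP) < 0.1
  drop[, !sporadic] <- FALSE
  peaks[drop] <- 0

  ## a zero effect or zero block correlation plants nothing: the truth
  ## ledger reflects the realized signal, not the requested slots
  if (config@effectSize == 0) {
    discG <- character(); discP <- character()
    shiftG <- shiftG[0, , drop = FALSE]; shiftP <- shiftP[0, , drop = FALSE]
  }
  if (config@blockCorr == 0) blocks <- list()
  truth <- list(
    genera = discG, peaks = discP,
    genusShifts = shiftG, peakShifts = shiftP,
    blocks = blocks, blockCorr = config@blockCorr,
    blockLoading = lam, blockResidualSD = sqrt(s2),
    rareGenera = gNames[rare],
    config = config
  )
  new("MultiOmicCohort", abundance = abundance, peaks = peaks,
      sampleData = md, truth = truth)
}

#' Null copy with metabolite-sample links broken
#'
#' Returns a copy of the cohort in which the rows of the peak table are
#' permuted as a block across samples: every marginal distribution and the
#' correlation structure *within* the metabolome are preserved, while any
#' association between genera (or metadata) and metabolites is destroyed.
#' Used to calibrate the type-I error of the permutation-corrected
#' cross-correlation.
#'
#' @param data a [MultiOmicCohort-class].
#' @param seed integer seed for the permutation.
#' @return A [MultiOmicCohort-class]; its truth ledger gains
#'   `nullPermuted = TRUE`.
#' @export
nullPermutedCopy <- function(data, seed) {
  stopifnot(is(data, "MultiOmicCohort"))
  set.seed(as.integer(seed))
  idx <- sample(nrow(data@peaks))
  pk <- data@peaks[idx, , drop = FALSE]
  rownames(pk) <- rownames(data@peaks)
  truth <- data@truth
  truth$nullPermuted <- TRUE
  initialize(data, peaks = pk, truth = truth)
}
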