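#' Simulate a two-block benchmark dataset
#'
#' Generates residue-pair-like examples with the statistical structure
#' the transductive transfer learner assumes: a weakly class-separating
#' sequence block observed everywhere and a strongly class-separating
#' atomic block observed in training rows only, cross-linked so that
#' sequence-space neighbours carry label-consistent atomic values.
#'
#' Labels take the configured positive fraction exactly (rounded), as
#' in a composition like "1000 (400 contact, 600 non-contact)".  The
#' sequence block is a spherical Gaussian with class means at
#' `+/- (seqSeparation/2) u` (`u` a fixed unit vector, `noiseSd`
#' within-class spread); the atomic block is
#' `+/- (atomicSeparation/2) v + crossLink * M s + noise`, where `M` is
#' a fixed random linear map with rows scaled so the sequence-driven
#' component has roughly unit variance, making `crossLink` directly
#' interpretable against `noiseSd`.  Test rows carry the sequence block
#' only; their true labels and atomic blocks are retained privately for
#' the oracle and for evaluation.
#'
#' @param nTrain,nTest numbers of labeled / unlabeled examples.
#' @param positiveFraction fraction of contacts (default 0.4).
#' @param dSeq,dAtomic block widths (defaults 10 and 2).
#' @param seqSeparation distance between class means in the sequence
#'   block, in units of the within-class standard deviation
#'   (default 1.3, placing the sequence-only optimum in the F1 ~ 0.7
#'   regime).
#' @param atomicSeparation same for the atomic block (default 6.0, a
#'   near-noiseless block when truly observed).
#' @param crossLink strength in `[0, 1]` of the sequence-to-atomic
#'   coupling (default 0.5).
#' @param noiseSd within-class standard deviation (default 1).
#' @param seed integer; the draw is fully reproducible from it.
#' @return a [ContactDataset-class] (train rows labeled with atomic
#'   blocks; test rows unlabeled with hidden truth retained).
#' @examples
#' d <- simulateContactData(nTrain = 100, nTest = 50, seed = 1)
#' table(exampleLabels(d)[isLabeled(d)])
#' @export
simulateContactData <- function(nTrain = 1000L, nTest = 1000L,
                                positiveFraction = 0.4,
                                dSeq = 10L, dAtomic = 2L,
                                seqSeparation = 1.3,
                                atomicSeparation = 6.0,
                                crossLink = 0.5, noiseSd = 1.0,
                                seed = 1L) {
  if (nTrain <= 0L || nTest < 0L) stop("counts must be positive")
  if (positiveFraction <= 0 || positiveFraction >= 1)
    stop("positiveFraction must lie in (0, 1)")
  if (seqSeparation < 0 || atomicSeparation < 0)
    stop("separations must be non-negative")
  nPosTr <- round(positiveFraction * nTrain)
  nPosTe <- round(positiveFraction * nTest)
  if (nPosTr == 0L || nPosTr == nTrain)
    stop("impossible composition: a class would be empty")
  withSeed(seed, {
    u <- c(1, rep(0, dSeq - 1L))
    v <- c(1, rep(0, dAtomic - 1L))
    M <- matrix(rnorm(dAtomic * dSeq, sd = 1 / sqrt(dSeq)), dAtomic, dSeq)
    n <- nTrain + nTest
    y <- c(sample(rep(c(1L, -1L), c(nPosTr, nTrain - nPosTr))),
           sample(rep(c(1L, -1L), c(nPosTe, nTest - nPosTe))))
    S <- matrix(rnorm(n * dSeq, sd = noiseSd), n, dSeq) +
      outer(y, u) * (seqSeparation / 2)
    A <- matrix(rnorm(n * dAtomic, sd = noiseSd), n, dAtomic) +
      outer(y, v) * (atomicSeparation / 2) + crossLink * S %*% t(M)
    isTrain <- c(rep(TRUE, nTrain), rep(FALSE, nTest))
    Apub <- A
    Apub[!isTrain, ] <- NA_real_
    contactDataset(
      seqFeatures = S, atomicFeatures = Apub,
      label = ifelse(isTrain, y, NA_integer_),
      ids = c(sprintf("tr%05d", seq_len(nTrain)),
              sprintf("te%05d", seq_len(nTest))),
      hiddenLabel = y, hiddenAtomic = A)
  })
}

#' Analytic and Monte-Carlo Bayes reference of the generator
#'
#' For the equal-covariance Gaussian design of
#' [simulateContactData()], the sequence-only Bayes error is available
#' in closed form (the optimal rule thresholds the coordinate along the
#' class-mean axis at `log((1-p)/p) * noiseSd^2 / seqSeparation`); the
#' full-view (sequence + truly observed atomic) error is estimated by
#' Monte Carlo with the exact linear discriminant.  Used to calibrate
#' the defaults and to bound what any learner can achieve.
#'
#' @inheritParams simulateContactData
#' @param nDraws Monte-Carlo sample size (default 1e5).
#' @return list with `seqError`, `fullError`, `seqF1`, `fullF1` (the F1
#'   values are Monte-Carlo estimates under the respective Bayes rule).
#' @export
bayesReference <- function(positiveFraction = 0.4, dSeq = 10L,
                           dAtomic = 2L, seqSeparation = 1.3,
                           atomicSeparation = 6.0, crossLink = 0.5,
                           noiseSd = 1.0, nDraws = 1e5, seed = 1L) {
  p <- positiveFraction
  seqError <- if (seqSeparation == 0) {
    min(p, 1 - p)
  } else {
    t0 <- log((1 - p) / p) * noiseSd^2 / seqSeparation
    p * pnorm((t0 - seqSeparation / 2) / noiseSd) +
      (1 - p) * (1 - pnorm((t0 + seqSeparation / 2) / noiseSd))
  }
  withSeed(seed + 7L, {
    u <- c(1, rep(0, dSeq - 1L))
    v <- c(1, rep(0, dAtomic - 1L))
    M <- matrix(rnorm(dAtomic * dSeq, sd = 1 / sqrt(dSeq)), dAtomic, dSeq)
    n <- as.integer(nDraws)
    y <- ifelse(stats::runif(n) < p, 1L, -1L)
    S <- matrix(rnorm(n * dSeq, sd = noiseSd), n, dSeq) +
      outer(y, u) * (seqSeparation / 2)
    A <- matrix(rnorm(n * dAtomic, sd = noiseSd), n, dAtomic) +
      outer(y, v) * (atomicSeparation / 2) + crossLink * S %*% t(M)
    X <- cbind(S, A)
    # exact joint covariance (equal across classes) and mean difference
    Sig <- rbind(
      cbind(diag(noiseSd^2, dSeq), noiseSd^2 * crossLink * t(M)),
      cbind(noiseSd^2 * crossLink * M,
            noiseSd^2 * crossLink^2 * M %*% t(M) +
              diag(noiseSd^2, dAtomic)))
    dMu <- c(seqSeparation * u,
             atomicSeparation * v + crossLink * M %*%
               (seqSeparation * u))
    wB <- solve(Sig, dMu)
    thr <- log((1 - p) / p)          # on the log-likelihood-ratio scale
    # class means are symmetric about the origin, so log-LR = wB . x
    llr <- drop(X %*% wB)
    predFull <- ifelse(llr > thr, 1L, -1L)
    llrSeq <- drop(S %*% (seqSeparation / noiseSd^2 * u))
    predSeq <- ifelse(llrSeq > thr, 1L, -1L)
    fullError <- mean(predFull != y)
    list(seqError = seqError, fullError = fullError,
         seqF1 = prf1(confusionCounts(predSeq, y))[["f1"]],
         fullF1 = prf1(confusionCounts(predFull, y))[["f1"]])
  })
}
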