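#' Initialize working labels with a sequence-only inductive SVM
#'
#' Fits an inductive soft-margin SVM on the labeled examples restricted
#' to the sequence block (the only block shared by labeled and unlabeled
#' examples, standardized by labeled statistics) and assigns each
#' unlabeled example the sign of its decision value.
#'
#' @param d a [ContactDataset-class]
#' @param C misclassification cost.
#' @param tol solver tolerance.
#' @return named integer vector of +1/-1 working labels over the
#'   unlabeled pool (empty if the pool is empty).
#' @export
initWorkingLabels <- function(d, C = 1, tol = 1e-6) {
  lab <- which(d@labeled)
  unl <- which(!d@labeled)
  if (!length(unl)) return(setNames(integer(0), character(0)))
  sc <- scaleStats(d@seqFeatures[lab, , drop = FALSE])
  S <- applyScale(d@seqFeatures, sc)
  m <- solveSoftMargin(S[lab, , drop = FALSE], d@label[lab],
                       penalties = penaltyState(C), tol = tol)
  f <- decisionValue(m, S[unl, , drop = FALSE])
  setNames(ifelse(f >= 0, 1L, -1L), d@ids[unl])
}

#' Class-conditional atomic feature means
#'
#' Arithmetic means of the atomic blocks of labeled contact (+1) and
#' non-contact (-1) examples, the proxies used to augment the unlabeled
#' pool before transductive training.
#'
#' @param d a [ContactDataset-class]
#' @return list with numeric vectors `posA` and `negA`.
#' @export
conditionalAtomicMeans <- function(d) {
  lab <- which(d@labeled)
  A <- d@atomicFeatures[lab, , drop = FALSE]
  y <- d@label[lab]
  if (!any(y == 1L)) stop("degenerate class: no labeled positives")
  if (!any(y == -1L)) stop("degenerate class: no labeled negatives")
  list(posA = colMeans(A[y == 1L, , drop = FALSE]),
       negA = colMeans(A[y == -1L, , drop = FALSE]))
}

#' Augment unlabeled examples with class-mean atomic blocks
#'
#' Completes the schema of every unlabeled example by assigning `posA`
#' to working-label +1 examples and `negA` to working-label -1 examples
#' (set `negativeMeans = "positive"` for the variant in which negatives
#' also receive the positive mean).
#'
#' @param d a [ContactDataset-class]
#' @param labels named working labels as from [initWorkingLabels()].
#' @param means list with `posA`/`negA` as from
#'   [conditionalAtomicMeans()].
#' @param negativeMeans which class mean negatives receive.
#' @return the unlabeled subset of `d` with atomic blocks filled in.
#' @export
augmentUnlabeled <- function(d, labels = initWorkingLabels(d),
                             means = conditionalAtomicMeans(d),
                             negativeMeans = c("negative", "positive")) {
  negativeMeans <- match.arg(negativeMeans)
  u <- d[which(!d@labeled)]
  if (!nExamples(u)) return(u)
  lu <- labels[u@ids]
  if (any(is.na(lu)))
    stop("working label unset for: ",
         paste(head(u@ids[is.na(lu)], 3L), collapse = ", "))
  negMean <- if (negativeMeans == "negative") means$negA else means$posA
  u@atomicFeatures <- t(vapply(lu, function(l)
    if (l == 1L) means$posA else negMean, numeric(length(means$posA))))
  dimnames(u@atomicFeatures) <- list(NULL, colnames(d@atomicFeatures))
  u
}

#' Label-switch eligibility of an unlabeled pair
#'
#' Two unlabeled examples qualify for a label swap when their working
#' labels differ, both violate their margins, and the slack sum exceeds
#' 2 strictly -- the condition under which exchanging the two labels
#' lowers the transductive objective at fixed `(w, b)`.
#'
#' @param xiM,xiL non-negative slacks of the two examples.
#' @param yM,yL their working labels (+1/-1).
#' @return logical (vectorized).
#' @export
swapEligible <- function(xiM, xiL, yM, yL) {
  if (any(xiM < 0) || any(xiL < 0)) stop("slacks must be non-negative")
  (yM * yL < 0) & (xiM > 0) & (xiL > 0) & (xiM + xiL > 2)
}

#' KNN update of an unlabeled example's atomic block
#'
#' Finds the `k` labeled examples of the matching class closest to the
#' example in the sequence-feature block (Euclidean distance, ties
#' broken by ascending example id) and returns the arithmetic mean of
#' their atomic blocks.  With `k` equal to the class size this reduces
#' to the global class mean of [conditionalAtomicMeans()].
#'
#' @param xSeq sequence-feature vector of the unlabeled example (in the
#'   same space as `d`'s sequence block).
#' @param label the example's current working label (+1/-1).
#' @param d a [ContactDataset-class] providing the labeled neighbours.
#' @param k neighbour count (clamped to the class size with a warning
#'   when fewer same-class examples exist).
#' @return numeric atomic vector.
#' @export
knnUpdateAtomic <- function(xSeq, label, d, k = 15L) {
  lab <- which(d@labeled)
  same <- lab[d@label[lab] == label]
  if (!length(same)) stop("no labeled examples of class ", label)
  if (length(same) < k) {
    warning("fewer than k = ", k, " labeled examples of class ", label,
            "; using all ", length(same), call. = FALSE)
    k <- length(same)
  }
  S <- d@seqFeatures[same, , drop = FALSE]
  d2 <- colSums((t(S) - xSeq)^2)
  nb <- same[order(d2, d@ids[same])][seq_len(k)]
  colMeans(d@atomicFeatures[nb, , drop = FALSE])
}

#' Double the unlabeled penalties towards their cap
#'
#' One annealing step of the outer loop:
#' `cPlus <- min(2 cPlus, cStar)` and likewise for `cMinus`.  The cap is
#' a fixed point, so the outer loop terminates.
#'
#' @param p a [penaltyState()]
#' @return the annealed penalty state.
#' @export
annealPenalties <- function(p) {
  p$cPlus <- min(2 * p$cPlus, p$cStar)
  p$cMinus <- min(2 * p$cMinus, p$cStar)
  p
}

#' Fit the transductive contact classifier
#'
#' Runs the full training procedure: a sequence-only inductive SVM
#' initializes the working labels of the unlabeled pool
#' ([initWorkingLabels()]); the pool is augmented with class-conditional
#' atomic means ([augmentUnlabeled()]); then nested loops switch
#' swap-eligible label pairs ([swapEligible()]), re-impute the atomic
#' block of every switched example from its k nearest same-class
#' neighbours ([knnUpdateAtomic()]), re-solve the margin problem
#' ([solveSoftMargin()]) and record history, while the outer loop
#' anneals the unlabeled penalties to their cap ([annealPenalties()]).
#'
#' @param d a [ContactDataset-class] with at least one labeled example
#'   of each class.
#' @param mode `"svm"` (inductive, sequence features only), `"tsvm"`
#'   (transductive, sequence features only) or `"attsvm"` (transductive
#'   with atomic-feature transfer).
#' @param C labeled-example cost (features are standardized internally
#'   using labeled statistics, so the default 1 is scale-free).
#' @param cStar target unlabeled cost; the unlabeled penalties start at
#'   `1e-3 * cStar` and double each outer iteration.
#' @param kKnn neighbour count of the transfer update (the useful range
#'   is about 10--20).
#' @param transfer `"knn"` for the local-mean update, `"classmean"` to
#'   re-assign the global class mean instead (ablation arm).
#' @param knnSpace block used for neighbour distances: `"sequence"`
#'   (default; the only measured block of unlabeled examples) or
#'   `"full"` (the augmented vector).
#' @param stopping `"none"` (run to the penalty cap), `"validation"`
#'   (hold out `nVal` labeled examples, stop at the F1 peak and restore
#'   the peak state) or `"active"` (delayed active learning: once the
#'   validation peak is detected -- or from iteration `startIteration`
#'   if given -- query the oracle for `queriesPerIteration` near-margin
#'   pool examples per iteration until no swap is eligible or the
#'   budget is exhausted).
#' @param nVal validation holdout size (default 20).
#' @param patience consecutive below-peak iterations before the peak is
#'   declared (default 2).
#' @param queriesPerIteration active-learning queries per iteration
#'   (default 2).
#' @param oracleBudget total query budget (default 100).
#' @param startIteration fixed start of active learning, or `NULL` for
#'   automatic (validation-peak) delay.
#' @param oracle function mapping example ids to true labels; defaults
#'   to the dataset's privately retained truth.
#' @param queryRanking `"margin"` queries the smallest `|f|` (most
#'   uncertain) examples; `"descending"` is the literal
#'   largest-`f`-first variant.
#' @param negativeMeans see [augmentUnlabeled()].
#' @param seed governs the validation draw; the core loop is
#'   deterministic.
#' @param tol solver duality-gap tolerance.
#' @param maxInnerFactor inner-iteration cap per outer iteration, as a
#'   multiple of the pool size.
#' @return an [ATTSVMFit-class]; see [predictedLabels()],
#'   [decisionValues()], [trainHistory()].
#' @examples
#' d <- simulateContactData(nTrain = 60, nTest = 40, seed = 7)
#' fit <- fitATTSVM(d, mode = "attsvm")
#' table(predictedLabels(fit))
#' @export
fitATTSVM <- function(d, mode = c("attsvm", "tsvm", "svm"),
                      C = 1, cStar = C, kKnn = 15L,
                      transfer = c("knn", "classmean"),
                      knnSpace = c("sequence", "full"),
                      stopping = c("none", "validation", "active"),
                      nVal = 20L, patience = 2L, queriesPerIteration = 2L,
                      oracleBudget = 100L, startIteration = NULL,
                      oracle = NULL,
                      queryRanking = c("margin", "descending"),
                      negativeMeans = c("negative", "positive"),
                      seed = 1L, tol = 1e-6, maxInnerFactor = 10L) {
  mode <- match.arg(mode)
  transfer <- match.arg(transfer)
  knnSpace <- match.arg(knnSpace)
  stopping <- match.arg(stopping)
  queryRanking <- match.arg(queryRanking)
  negativeMeans <- match.arg(negativeMeans)
  viol <- validateDataset(d)
  if (length(viol))
    stop("invalid dataset:\n  ", paste(head(viol, 5L), collapse = "\n  "))
  config <- list(mode = mode, C = C, cStar = cStar, kKnn = kKnn,
                 transfer = transfer, knnSpace = knnSpace,
                 stopping = stopping, nVal = nVal, patience = patience,
                 queriesPerIteration = queriesPerIteration,
                 oracleBudget = oracleBudget,
                 startIteration = startIteration,
                 queryRanking = queryRanking,
                 negativeMeans = negativeMeans, seed = seed, tol = tol)

  needVal <- stopping == "validation" ||
    (stopping == "active" && is.null(startIteration))
  if (needVal) {
    sv <- splitValidation(d, nVal, seed)
    train <- sv$train
    val <- sv$validation
  } else {
    train <- d
    val <- NULL
  }
  if (is.null(oracle)) {
    truth <- hiddenLabels(d)
    oracle <- function(ids) {
      out <- truth[ids]
      if (any(is.na(out)))
        stop("oracle has no label for: ",
             paste(ids[is.na(out)], collapse = ", "))
      out
    }
  }

  lab <- which(train@labeled)
  unl <- which(!train@labeled)
  yl <- train@label[lab]
  idsU <- train@ids[unl]

  scS <- scaleStats(train@seqFeatures[lab, , drop = FALSE])
  S <- applyScale(train@seqFeatures, scS)
  scA <- scaleStats(train@atomicFeatures[lab, , drop = FALSE])
  A <- applyScale(train@atomicFeatures, scA)
  dSeq <- ncol(S)
  scaling <- list(seqCenter = scS$center, seqScale = scS$scale,
                  atomicCenter = scA$center, atomicScale = scA$scale)

  # inductive initialization on the sequence block
  m0 <- solveSoftMargin(S[lab, , drop = FALSE], yl,
                        penalties = penaltyState(C), tol = tol)
  f0 <- if (length(unl)) decisionValue(m0, S[unl, , drop = FALSE])
        else numeric(0)
  wl <- as.integer(ifelse(f0 >= 0, 1L, -1L))

  hist0 <- data.frame(iteration = 1L, cPlus = NA_real_, cMinus = NA_real_,
                      nSwaps = 0L, objective = svmObjective(m0),
                      valF1 = NA_real_, nQueries = 0L, testF1 = NA_real_)
  if (mode == "svm" || !length(unl)) {
    return(new("ATTSVMFit", model = m0, mode = mode,
               workingLabels = setNames(wl, idsU),
               decision = setNames(f0, idsU), history = hist0,
               transfer = list(), queried = character(0),
               scaling = scaling, stoppedAt = NA_integer_,
               config = config))
  }

  means <- list(posA = colMeans(A[lab, , drop = FALSE][yl == 1L, ,
                                                       drop = FALSE]),
                negA = colMeans(A[lab, , drop = FALSE][yl == -1L, ,
                                                       drop = FALSE]))
  negMean0 <- if (negativeMeans == "negative") means$negA else means$posA
  if (mode == "attsvm") {
    imputed <- t(vapply(wl, function(l) if (l == 1L) means$posA
                        else negMean0, numeric(ncol(A))))
    XL <- cbind(S[lab, , drop = FALSE], A[lab, , drop = FALSE])
    XU <- cbind(S[unl, , drop = FALSE], imputed)
  } else {
    XL <- S[lab, , drop = FALSE]
    XU <- S[unl, , drop = FALSE]
  }
  rownames(XL) <- train@ids[lab]
  rownames(XU) <- idsU
  nL <- nrow(XL)
  nU <- nrow(XU)
  kKnn <- max(1L, min(as.integer(kKnn), sum(yl == 1L), sum(yl == -1L)))

  # transfer update for one pool row (index into XU); returns atomic vec
  labSeq <- S[lab, , drop = FALSE]
  labAtomic <- A[lab, , drop = FALSE]
  idsL <- train@ids[lab]
  transferUpdate <- function(i) {
    cls <- wl[i]
    if (transfer == "classmean")
      return(if (cls == 1L) means$posA else means$negA)
    same <- which(yl == cls)
    ref <- if (knnSpace == "sequence") labSeq else XL
    qry <- if (knnSpace == "sequence") S[unl[i], ] else XU[i, ]
    d2 <- colSums((t(ref[same, , drop = FALSE]) - qry)^2)
    nb <- same[order(d2, idsL[same])][seq_len(min(kKnn, length(same)))]
    colMeans(labAtomic[nb, , drop = FALSE])
  }

  # validation predictor
  valF1 <- function(m) {
    if (is.null(val) || !nExamples(val)) return(NA_real_)
    Xv <- applyScale(val@seqFeatures, scS)
    if (mode == "attsvm")
      Xv <- cbind(Xv, applyScale(val@atomicFeatures, scA))
    pred <- ifelse(decisionValue(m, Xv) >= 0, 1L, -1L)
    prf1(confusionCounts(pred, val@label))[["f1"]]
  }
  hidden <- train@hiddenLabel[unl]
  testF1 <- function(keep) {
    ok <- keep & !is.na(hidden)
    if (!any(ok)) return(NA_real_)
    prf1(confusionCounts(wl[ok], hidden[ok]))[["f1"]]
  }

  fixedU <- rep(FALSE, nU)          # pool rows revealed by the oracle
  queried <- character(0)
  budget <- oracleBudget
  pen <- penaltyState(C, cStar)
  alpha <- NULL
  hist <- vector("list", 256L)
  nHist <- 0L
  iter <- 0L
  snap <- NULL                       # best-validation snapshot
  stoppedAt <- NA_integer_
  alActive <- FALSE
  stopRun <- FALSE
  outerMax <- ceiling(log2(pen$cStar / pen$cPlus)) + 5L

  resolve <- function() {
    Cvec <- c(rep(C, nL),
              ifelse(fixedU, C, ifelse(wl == 1L, pen$cPlus, pen$cMinus)))
    yAll <- c(yl, wl)
    a0 <- if (is.null(alpha)) numeric(nL + nU) else alpha
    sol <- .smoSolve(rbind(XL, XU), as.integer(yAll), Cvec, tol,
                     max(500L * (nL + nU), 200000L), a0)
    alpha <<- drop(sol$alpha)
    w <- setNames(drop(sol$w), colnames(XL))
    f <- drop(rbind(XL, XU) %*% w + sol$b)
    xi <- pmax(0, 1 - yAll * f)
    m <- new("MarginModel", w = w, b = sol$b,
             slackLabeled = setNames(xi[seq_len(nL)], idsL),
             slackUnlabeled = setNames(xi[-seq_len(nL)], idsU),
             unlabeledLabels = setNames(as.integer(wl), idsU),
             penalties = unclass(pen))
    list(m = m, fU = f[-seq_len(nL)], xiU = xi[-seq_len(nL)])
  }
  objectiveOf <- function(st) {
    # queried rows are charged at the labeled cost C
    p <- st$m@penalties
    xiU <- st$m@slackUnlabeled
    0.5 * sum(st$m@w^2) + p$C * sum(st$m@slackLabeled) +
      p$C * sum(xiU[fixedU]) +
      p$cPlus * sum(xiU[!fixedU & wl == 1L]) +
      p$cMinus * sum(xiU[!fixedU & wl == -1L])
  }
  record <- function(st, nSwaps, nQueries) {
    iter <<- iter + 1L
    v <- valF1(st$m)
    nHist <<- nHist + 1L
    hist[[nHist]] <<- data.frame(
      iteration = iter, cPlus = pen$cPlus, cMinus = pen$cMinus,
      nSwaps = nSwaps, objective = objectiveOf(st), valF1 = v,
      nQueries = nQueries, testF1 = testF1(!fixedU & train@evalEligible[unl]))
    if (!is.na(v) && (is.null(snap) || v > snap$valF1))
      snap <<- list(valF1 = v, wl = wl, m = st$m, iter = iter,
                    imputed = if (mode == "attsvm")
                      XU[, dSeq + seq_len(ncol(A)), drop = FALSE])
    # peak monitoring
    if (stopping != "none" && needVal) {
      vs <- vapply(hist[seq_len(nHist)], function(h) h$valF1, 0)
      pk <- detectPeak(vs[!is.na(vs)], patience)
      if (!is.na(pk)) {
        if (stopping == "validation") {
          stopRun <<- TRUE
          stoppedAt <<- snap$iter
        } else if (!alActive) {
          alActive <<- TRUE
        }
      }
    }
    if (stopping == "active" && !is.null(startIteration) &&
        iter >= startIteration)
      alActive <<- TRUE
  }

  st <- NULL
  for (outer in seq_len(outerMax)) {
    st <- resolve()
    record(st, 0L, 0L)
    if (stopRun) break
    innerMax <- maxInnerFactor * nU
    for (inner in seq_len(innerMax)) {
      # most violating opposite pair among unrevealed pool examples
      free <- !fixedU
      posC <- which(free & wl == 1L & st$xiU > 0)
      negC <- which(free & wl == -1L & st$xiU > 0)
      if (!length(posC) || !length(negC)) break
      i <- posC[order(-st$xiU[posC], idsU[posC])][1L]
      j <- negC[order(-st$xiU[negC], idsU[negC])][1L]
      if (!swapEligible(st$xiU[i], st$xiU[j], 1L, -1L)) break
      wl[i] <- -1L
      wl[j] <- 1L
      if (mode == "attsvm") {
        XU[i, dSeq + seq_len(ncol(A))] <- transferUpdate(i)
        XU[j, dSeq + seq_len(ncol(A))] <- transferUpdate(j)
      }
      alpha[nL + c(i, j)] <- 0
      nq <- 0L
      if (alActive && budget > 0L) {
        k <- min(queriesPerIteration, budget, sum(!fixedU))
        if (k > 0L) {
          sel <- selectQueries(st$fU[!fixedU], idsU[!fixedU], k,
                               ranking = queryRanking)
          selIdx <- match(sel, idsU)
          revealed <- oracle(sel)
          wl[selIdx] <- as.integer(revealed)
          fixedU[selIdx] <- TRUE
          alpha[nL + selIdx] <- 0
          queried <- c(queried, sel)
          budget <- budget - k
          nq <- k
        }
      }
      st <- resolve()
      record(st, 1L, nq)
      if (stopRun) break
      if (nq > 0L) {
        # AL termination: queries issued and no further eligible swap
        free <- !fixedU
        xp <- st$xiU[free & wl == 1L]
        xn <- st$xiU[free & wl == -1L]
        noSwap <- !length(xp) || !length(xn) ||
          max(xp) <= 0 || max(xn) <= 0 || max(xp) + max(xn) <= 2
        if (noSwap || budget == 0L) {
          stopRun <- TRUE
          stoppedAt <- iter
        }
      }
      if (stopRun) break
    }
    if (stopRun) break
    if (pen$cPlus >= pen$cStar && pen$cMinus >= pen$cStar) break
    pen <- annealPenalties(pen)
  }

  if (stopping == "validation" && !is.null(snap) && !is.na(stoppedAt)) {
    wl <- snap$wl
    st$m <- snap$m
    if (mode == "attsvm" && !is.null(snap$imputed))
      XU[, dSeq + seq_len(ncol(A))] <- snap$imputed
    st$fU <- drop(XU %*% st$m@w + st$m@b)
  }

  history <- do.call(rbind, hist[seq_len(nHist)])
  transferState <- if (mode == "attsvm")
    list(posA = means$posA, negA = means$negA,
         imputed = XU[, dSeq + seq_len(ncol(A)), drop = FALSE],
         kKnn = kKnn)
    else list()
  new("ATTSVMFit", model = st$m, mode = mode,
      workingLabels = setNames(as.integer(wl), idsU),
      decision = setNames(drop(XU %*% st$m@w + st$m@b), idsU),
      history = history, transfer = transferState, queried = queried,
      scaling = scaling, stoppedAt = stoppedAt, config = config)
}

#' Accessors for a fitted transductive run
#'
#' @param fit an [ATTSVMFit-class]
#' @return `predictedLabels`: named +1/-1 labels of the unlabeled pool
#'   (the final working labels); `decisionValues`: named decision
#'   values; `trainHistory`: the per-iteration history data.frame;
#'   `queriedIds`: ids revealed by the oracle (evaluation-ineligible).
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
predictedLabels <- function(fit) fit@workingLabels
#' @rdname fit-accessors
#' @export
decisionValues <- function(fit) fit@decision
#' @rdname fit-accessors
#' @export
trainHistory <- function(fit) fit@history
#' @rdname fit-accessors
#' @export
queriedIds <- function(fit) fit@queried

#' @export
setMethod("show", "ATTSVMFit", function(object) {
  h <- object@history
  cat(sprintf("ATTSVMFit (mode = %s): %d pool examples, %d iterations\n",
              object@mode, length(object@workingLabels), nrow(h)))
  cat(sprintf("  swaps: %d, oracle queries: %d, final objective: %.4g\n",
              sum(h$nSwaps), length(object@queried),
              h$objective[nrow(h)]))
  if (!is.na(object@stoppedAt))
    cat(sprintf("  stopped early at iteration %d\n", object@stoppedAt))
  invisible(NULL)
})

# column-wise center/scale statistics (sd 0 guarded to 1)
scaleStats <- function(X) {
  ctr <- colMeans(X, na.rm = TRUE)
  scl <- apply(X, 2L, sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  ctr[!is.finite(ctr)] <- 0
  list(center = ctr, scale = scl)
}
applyScale <- function(X, st)
  sweep(sweep(X, 2L, st$center), 2L, st$scale, "/")
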