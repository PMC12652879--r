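#' Penalty state for the three-way misclassification costs
#'
#' The transductive objective charges labeled examples at cost `C` and
#' unlabeled examples at `cPlus` or `cMinus` depending on their current
#' working label; `cStar` is the target cap both unlabeled costs are
#' annealed towards.
#'
#' @param C labeled-example cost (default 1 on standardized features).
#' @param cStar target unlabeled cost (defaults to `C`).
#' @param cPlus,cMinus current unlabeled costs (default `1e-3 * cStar`,
#'   the usual small start of the annealing loop).
#' @return a validated list with class `"PenaltyState"`.
#' @seealso [annealPenalties()]
#' @export
penaltyState <- function(C = 1, cStar = C, cPlus = 1e-3 * cStar,
                         cMinus = 1e-3 * cStar) {
  p <- list(C = C, cPlus = cPlus, cMinus = cMinus, cStar = cStar)
  if (any(unlist(p) <= 0)) stop("all penalties must be strictly positive")
  if (cPlus > cStar + 1e-12 || cMinus > cStar + 1e-12)
    stop("cPlus and cMinus must not exceed cStar")
  class(p) <- "PenaltyState"
  p
}

#' Solve the soft-margin SVM with per-example costs
#'
#' The `solve-svm-qp` primitive of the transductive loop: minimizes
#' \deqn{\tfrac12\|w\|^2 + C\sum_i \xi_i
#'   + C^*_-\sum_{j: y^*_j=-1} \xi^*_j
#'   + C^*_+\sum_{j: y^*_j=+1} \xi^*_j}
#' over a linear hyperplane `(w, b)` for a fixed label assignment, via
#' sequential minimal optimization on the dual.  No feature scaling is
#' applied here; the training pipeline standardizes beforehand.
#'
#' @param labeledX numeric matrix of labeled feature rows (complete
#'   vectors).
#' @param labeledY integer +1/-1 labels.
#' @param unlabeledX optional matrix of unlabeled rows, already
#'   augmented to the full schema.
#' @param unlabeledY working labels of the unlabeled rows.
#' @param penalties a [penaltyState()].
#' @param tol duality-gap tolerance of the solver (default 1e-6).
#' @param alphaStart optional dual warm start, length
#'   `nrow(labeledX) + nrow(unlabeledX)`.
#' @return a [MarginModel-class]; the attribute-free dual solution is
#'   attached as `attr(, "alpha")` for warm-starting.
#' @examples
#' m <- solveSoftMargin(matrix(c(2, -2)), c(1L, -1L),
#'                      penalties = penaltyState(C = 1e6))
#' c(m@w, m@b)   # 0.5, 0
#' @export
solveSoftMargin <- function(labeledX, labeledY, unlabeledX = NULL,
                            unlabeledY = NULL, penalties = penaltyState(),
                            tol = 1e-6, alphaStart = NULL) {
  labeledX <- as.matrix(labeledX)
  labeledY <- as.integer(labeledY)
  if (length(unique(labeledY[!is.na(labeledY)])) < 2L)
    stop("degenerate problem: labeled examples must contain both classes")
  if (is.null(unlabeledX)) {
    unlabeledX <- matrix(numeric(0), 0L, ncol(labeledX))
    unlabeledY <- integer(0)
  }
  unlabeledX <- as.matrix(unlabeledX)
  unlabeledY <- as.integer(unlabeledY)
  if (nrow(unlabeledX) != length(unlabeledY))
    stop("unlabeledY length disagrees with unlabeledX")
  X <- rbind(labeledX, unlabeledX)
  y <- c(labeledY, unlabeledY)
  if (!all(is.finite(X))) stop("non-finite feature value")
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  Cvec <- c(rep(penalties$C, nrow(labeledX)),
            ifelse(unlabeledY == 1L, penalties$cPlus, penalties$cMinus))
  if (is.null(alphaStart)) alphaStart <- numeric(nrow(X))
  sol <- .smoSolve(X, y, Cvec, tol, max(500L * nrow(X), 200000L),
                   alphaStart)
  if (!sol$converged)
    warning("SMO solver hit the iteration cap before reaching tolerance")
  w <- drop(sol$w)
  names(w) <- colnames(X)
  f <- drop(X %*% w + sol$b)
  xi <- pmax(0, 1 - y * f)
  nl <- nrow(labeledX)
  idsL <- rownames(labeledX)
  if (is.null(idsL)) idsL <- paste0("L", seq_len(nl))
  idsU <- rownames(unlabeledX)
  if (is.null(idsU) && nrow(unlabeledX))
    idsU <- paste0("U", seq_len(nrow(unlabeledX)))
  m <- new("MarginModel", w = w, b = sol$b,
           slackLabeled = setNames(xi[seq_len(nl)], idsL),
           slackUnlabeled = setNames(xi[-seq_len(nl)], idsU),
           unlabeledLabels = setNames(unlabeledY, idsU),
           penalties = unclass(penalties))
  attr(m, "alpha") <- drop(sol$alpha)
  m
}

#' Signed decision value of a linear margin model
#'
#' `w . x + b`; the sign is the predicted label and the magnitude is the
#' margin distance scaled by `||w||`.
#'
#' @param m a [MarginModel-class]
#' @param x a feature vector, or a matrix of row vectors.
#' @return numeric vector of decision values.
#' @examples
#' m <- new("MarginModel", w = c(1, 0), b = -1, slackLabeled = numeric(0),
#'          slackUnlabeled = numeric(0), unlabeledLabels = integer(0),
#'          penalties = unclass(penaltyState()))
#' decisionValue(m, c(3, 7))   # 2
#' @export
decisionValue <- function(m, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(m@w))
    stop("schema mismatch: expected ", length(m@w), " features, got ",
         ncol(x))
  drop(x %*% m@w + m@b)
}

#' Hinge slack of an example under a model
#'
#' `max(0, 1 - y * f(x))`: zero outside the margin, 1 on the hyperplane,
#' above 1 when misclassified.
#'
#' @inheritParams decisionValue
#' @param y label(s) in +1/-1.
#' @return non-negative numeric.
#' @export
slackOf <- function(m, x, y) {
  if (!all(y %in% c(-1, 1))) stop("y must be +1 or -1")
  pmax(0, 1 - y * decisionValue(m, x))
}

#' Value of the transductive objective at a model state
#'
#' `0.5 ||w||^2 + C sum(xi) + cMinus sum(xi*[y* = -1]) +
#' cPlus sum(xi*[y* = +1])`, computed from the slack maps stored in the
#' model.
#'
#' @param m a [MarginModel-class]
#' @return numeric(1)
#' @export
svmObjective <- function(m) {
  p <- m@penalties
  yU <- m@unlabeledLabels
  0.5 * sum(m@w^2) + p$C * sum(m@slackLabeled) +
    p$cMinus * sum(m@slackUnlabeled[yU == -1L]) +
    p$cPlus * sum(m@slackUnlabeled[yU == 1L])
}
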