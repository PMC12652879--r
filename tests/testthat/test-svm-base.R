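test_that("the symmetric separable pair gives margin planes at +/-1", {
  m <- solveSoftMargin(matrix(c(2, -2)), c(1L, -1L),
                       penalties = penaltyState(C = 1e6))
  expect_equal(unname(m@w), 0.5, tolerance = 1e-8)
  expect_equal(m@b, 0, tolerance = 1e-8)
  expect_equal(unname(m@slackLabeled), c(0, 0), tolerance = 1e-8)
})

test_that("an empty unlabeled set reduces to the plain soft-margin SVM", {
  set.seed(1)
  X <- matrix(rnorm(40), 20L)
  y <- rep(c(1L, -1L), 10L)
  X[, 1L] <- X[, 1L] + y
  m1 <- solveSoftMargin(X, y)
  m2 <- solveSoftMargin(X, y, unlabeledX = matrix(numeric(0), 0L, 2L),
                        unlabeledY = integer(0))
  expect_equal(m1@w, m2@w)
  expect_equal(m1@b, m2@b)
  expect_equal(svmObjective(m1), svmObjective(m2))
})

test_that("objective matches an independent QP oracle on a 6-point instance", {
  skip_if_not_installed("kernlab")
  set.seed(7)
  X <- matrix(rnorm(12), 6L)
  yL <- c(1L, -1L, 1L)
  yU <- c(1L, -1L, -1L)
  pen <- penaltyState(C = 2, cStar = 2, cPlus = 0.7, cMinus = 0.3)
  m <- solveSoftMargin(X[1:3, ], yL, X[4:6, ], yU, penalties = pen)

  # generic interior-point QP on the dual:
  #   min -1'a + a' Q a / 2,  y'a = 0,  0 <= a <= C_i
  y <- c(yL, yU)
  Cvec <- c(rep(2, 3L), ifelse(yU == 1L, 0.7, 0.3))
  Q <- (y %o% y) * (X %*% t(X))
  sol <- kernlab::ipop(c = rep(-1, 6L), H = Q,
                       A = matrix(as.numeric(y), 1L), b = 0,
                       l = rep(0, 6L), u = Cvec, r = 0, sigf = 9)
  a <- kernlab::primal(sol)
  dualObj <- sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
  expect_equal(svmObjective(m), dualObj, tolerance = 1e-6)
})

test_that("no feasible hyperplane beats the solver objective", {
  set.seed(3)
  X <- matrix(rnorm(30), 15L)
  y <- rep(c(1L, -1L), length.out = 15L)
  X[, 1L] <- X[, 1L] + 0.8 * y
  pen <- penaltyState(C = 1.5)
  m <- solveSoftMargin(X, y, penalties = pen)
  objAt <- function(w, b) {
    0.5 * sum(w^2) + pen$C * sum(pmax(0, 1 - y * (X %*% w + b)))
  }
  for (i in 1:100) {
    w <- rnorm(2L, sd = 2)
    b <- rnorm(1L, sd = 2)
    expect_gte(objAt(w, b), svmObjective(m) - 1e-8)
  }
})

test_that("doubling penalties never adds margin violations when separable", {
  set.seed(8)
  X <- matrix(rnorm(24), 12L)
  y <- rep(c(1L, -1L), 6L)
  X[, 1L] <- X[, 1L] + 3 * y     # comfortably separable
  nViol <- function(C) {
    m <- solveSoftMargin(X, y, penalties = penaltyState(C = C))
    sum(m@slackLabeled > 1e-8)
  }
  for (C in c(0.25, 0.5, 1, 2, 4))
    expect_gte(nViol(C), nViol(2 * C))
})

test_that("decision values are affine and match recomputation", {
  m <- solveSoftMargin(matrix(c(2, -2, 1, -1, 0.5, -0.5), ncol = 2L),
                       c(1L, -1L, 1L))
  expect_equal(decisionValue(m, c(3, 7)), sum(m@w * c(3, 7)) + m@b)
  set.seed(4)
  X <- matrix(rnorm(200), 100L)
  expect_equal(decisionValue(m, X),
               apply(X, 1L, function(x) sum(m@w * x) + m@b))
  x1 <- c(1, 2); x2 <- c(-3, 0.5)
  for (a in c(0, 0.3, 1, 1.7))
    expect_equal(decisionValue(m, a * x1 + (1 - a) * x2),
                 a * decisionValue(m, x1) + (1 - a) * decisionValue(m, x2))
  expect_error(decisionValue(m, c(1, 2, 3)), "schema mismatch")
})

test_that("slack follows the hinge and the model state is consistent", {
  m <- new("MarginModel", w = c(1, 0), b = -1, slackLabeled = numeric(0),
           slackUnlabeled = numeric(0), unlabeledLabels = integer(0),
           penalties = unclass(penaltyState()))
  expect_equal(slackOf(m, c(3, 0), 1), 0)    # decision +2, outside margin
  expect_equal(slackOf(m, c(1, 5), 1), 1)    # on the hyperplane
  expect_equal(slackOf(m, c(0.5, 0), 1), 1.5)  # misclassified
  expect_error(slackOf(m, c(1, 0), 0), "must be \\+1 or -1")

  # stored slacks equal max(0, 1 - y f(x)) at the solution
  set.seed(5)
  X <- matrix(rnorm(40), 20L)
  y <- rep(c(1L, -1L), 10L)
  fit <- solveSoftMargin(X, y)
  expect_equal(unname(fit@slackLabeled),
               unname(slackOf(fit, X, y)), tolerance = 1e-8)
})

test_that("the objective matches term-by-term recomputation", {
  m <- new("MarginModel", w = c(1, 0), b = 2, slackLabeled = numeric(0),
           slackUnlabeled = numeric(0), unlabeledLabels = integer(0),
           penalties = unclass(penaltyState()))
  expect_equal(svmObjective(m), 0.5)
  m@slackLabeled <- c(a = 0.5, b = 0.25)
  expect_equal(svmObjective(m), 0.5 + 0.75)
  set.seed(6)
  m@w <- rnorm(2)
  m@slackLabeled <- abs(rnorm(5))
  m@slackUnlabeled <- abs(rnorm(4))
  m@unlabeledLabels <- c(1L, -1L, -1L, 1L)
  m@penalties <- list(C = 1.3, cPlus = 0.2, cMinus = 0.4, cStar = 1.3)
  expect_equal(svmObjective(m),
               0.5 * sum(m@w^2) + 1.3 * sum(m@slackLabeled) +
                 0.4 * sum(m@slackUnlabeled[c(2, 3)]) +
                 0.2 * sum(m@slackUnlabeled[c(1, 4)]))
})

test_that("degenerate inputs are rejected", {
  expect_error(solveSoftMargin(matrix(1:3), c(1L, 1L, 1L)),
               "both classes")
  expect_error(solveSoftMargin(matrix(c(1, NA)), c(1L, -1L)),
               "non-finite")
})
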