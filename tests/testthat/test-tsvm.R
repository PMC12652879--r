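test_that("working-label initialization follows the sequence hyperplane", {
  d <- tinyDataset(nL = 10L, nU = 3L)
  # make an unlabeled example's sequence block identical to a deep
  # positive labeled one: it must land on the same side
  posRow <- which(d@label == 1L)[1L]
  d@seqFeatures[11L, ] <- d@seqFeatures[posRow, ] +
    5 * sign(d@seqFeatures[posRow, 1L])
  d@seqFeatures[posRow, ] <- d@seqFeatures[11L, ]
  wl <- initWorkingLabels(d)
  expect_length(wl, 3L)
  expect_identical(unname(wl[1L]), 1L)

  # linearly separable pool: working labels recover the hidden truth
  ds <- simulateContactData(nTrain = 80L, nTest = 60L,
                            seqSeparation = 8, seed = 3L)
  wls <- initWorkingLabels(ds)
  expect_identical(unname(wls),
                   unname(hiddenLabels(ds)[!isLabeled(ds)]))

  dEmpty <- tinyDataset(nL = 6L, nU = 0L)
  expect_length(initWorkingLabels(dEmpty), 0L)
})

test_that("class-conditional atomic means are arithmetic means", {
  d <- contactDataset(matrix(0, 3L, 2L),
                      rbind(c(1, 3), c(3, 5), c(0, 0)),
                      label = c(1L, 1L, -1L))
  m <- conditionalAtomicMeans(d)
  expect_equal(unname(m$posA), c(2, 4))
  expect_equal(unname(m$negA), c(0, 0))

  d1 <- d[c(1L, 3L)]
  m1 <- conditionalAtomicMeans(d1)
  expect_equal(unname(m1$posA), c(1, 3))   # single example per class

  # 500 generated examples against a brute-force accumulation
  dBig <- simulateContactData(nTrain = 500L, nTest = 5L, seed = 6L)
  mB <- conditionalAtomicMeans(dBig)
  A <- atomicFeatures(dBig)[isLabeled(dBig), ]
  y <- dBig@label[isLabeled(dBig)]
  acc <- c(0, 0); k <- 0L
  for (i in seq_along(y)) if (y[i] == 1L) { acc <- acc + A[i, ]; k <- k + 1L }
  expect_equal(unname(mB$posA), unname(acc / k))

  expect_error(conditionalAtomicMeans(d[1:2]), "degenerate class")
})

test_that("augmentation assigns class means by working label", {
  d <- tinyDataset(nL = 6L, nU = 2L)
  means <- conditionalAtomicMeans(d)
  ids <- exampleIds(d)[!isLabeled(d)]
  lab <- setNames(c(1L, -1L), ids)
  u <- augmentUnlabeled(d, lab, means)
  expect_equal(unname(atomicFeatures(u)[1L, ]), unname(means$posA))
  expect_equal(unname(atomicFeatures(u)[2L, ]), unname(means$negA))

  lab2 <- setNames(c(1L, 1L), ids)
  u2 <- augmentUnlabeled(d, lab2, means)
  expect_true(all(t(atomicFeatures(u2)) == means$posA))

  expect_identical(atomicFeatures(augmentUnlabeled(d, lab, means)),
                   atomicFeatures(u))          # idempotent
  expect_error(augmentUnlabeled(d, setNames(c(1L, NA), ids), means),
               "unset")
  # literal variant: negatives get the positive mean
  u3 <- augmentUnlabeled(d, lab, means, negativeMeans = "positive")
  expect_equal(unname(atomicFeatures(u3)[2L, ]), unname(means$posA))
})

test_that("the swap condition is strict and label-opposed", {
  expect_true(swapEligible(1.5, 0.8, 1L, -1L))      # sum 2.3 > 2
  expect_false(swapEligible(1.5, 0.5, 1L, -1L))     # sum exactly 2
  expect_false(swapEligible(1.5, 0.8, 1L, 1L))      # same labels
  expect_false(swapEligible(2.5, 0, 1L, -1L))       # one slack zero
  expect_error(swapEligible(-0.1, 1, 1L, -1L), "non-negative")
})

test_that("KNN atomic update matches the exhaustive sort oracle", {
  d <- tinyDataset(nL = 10L, nU = 2L, seed = 9L)
  x <- seqFeatures(d)[11L, ]
  # k = 1: the single nearest same-class neighbour's atomic vector
  one <- knnUpdateAtomic(x, 1L, d, k = 1L)
  expect_equal(one, oracleKnn(x, 1L, d, 1L))
  # k = class size reduces to the conditional class mean
  all5 <- knnUpdateAtomic(x, -1L, d, k = 5L)
  expect_equal(unname(all5), unname(conditionalAtomicMeans(d)$negA))
  # k = 3 on random instances
  for (i in 1:100) {
    di <- tinyDataset(nL = sample(6:12, 1L), nU = 1L, seed = i)
    xi <- seqFeatures(di)[nExamples(di), ]
    lab <- sample(c(-1L, 1L), 1L)
    expect_equal(knnUpdateAtomic(xi, lab, di, 3L),
                 oracleKnn(xi, lab, di, 3L))
  }
  # shortfall falls back to all same-class examples with a warning
  expect_warning(res <- knnUpdateAtomic(x, 1L, d, k = 50L),
                 "fewer than k")
  expect_equal(unname(res), unname(conditionalAtomicMeans(d)$posA))
})

test_that("annealing doubles towards the cap and stops there", {
  p <- penaltyState(C = 1, cStar = 1, cPlus = 0.001, cMinus = 0.25)
  p1 <- annealPenalties(p)
  expect_equal(p1$cPlus, 0.002)
  expect_equal(p1$cMinus, 0.5)
  p2 <- annealPenalties(annealPenalties(p1))
  expect_equal(p2$cMinus, 1)                       # capped
  expect_identical(annealPenalties(p2)$cMinus, 1)  # fixed point
})

test_that("an empty pool degenerates to the inductive model", {
  d <- tinyDataset(nL = 12L, nU = 0L)
  fit <- fitATTSVM(d, mode = "attsvm")
  ind <- fitATTSVM(d, mode = "svm")
  expect_equal(fit@model@w, ind@model@w)
  expect_equal(fit@model@b, ind@model@b)
  expect_length(predictedLabels(fit), 0L)
})

test_that("label switching corrects a mis-initialized clustered pool", {
  d <- liveInstance()
  ind <- evaluateFit(fitATTSVM(d, mode = "svm"), d)
  fit <- fitATTSVM(d, mode = "tsvm")
  tr <- evaluateFit(fit, d)
  h <- trainHistory(fit)
  expect_gt(sum(h$nSwaps), 0L)
  expect_gt(tr$f1, ind$f1 + 0.1)
  expect_identical(objectiveViolations(h), 0L)
})

test_that("objective never increases across swaps at fixed penalties", {
  # exercised on instances where swaps actually fire
  for (s in 1:3) {
    d <- liveInstance(seed = s)
    for (m in c("tsvm", "attsvm")) {
      h <- trainHistory(fitATTSVM(d, mode = m))
      expect_identical(objectiveViolations(h), 0L)
    }
  }
})

test_that("imputed atomic vectors stay in the labeled class envelope", {
  d <- simulateContactData(nTrain = 60L, nTest = 40L,
                           atomicSeparation = 1.5, seed = 2L)
  fit <- fitATTSVM(d, mode = "attsvm", kKnn = 5L)
  imp <- fit@transfer$imputed
  # bounding box of standardized labeled atomic values, per class
  A <- atomicFeatures(d)[isLabeled(d), ]
  As <- scale(A)
  y <- d@label[isLabeled(d)]
  wl <- predictedLabels(fit)
  for (cls in c(-1L, 1L)) {
    box <- As[y == cls, , drop = FALSE]
    rows <- imp[wl == cls, , drop = FALSE]
    for (jj in seq_len(ncol(rows))) {
      expect_true(all(rows[, jj] >= min(box[, jj]) - 1e-8))
      expect_true(all(rows[, jj] <= max(box[, jj]) + 1e-8))
    }
  }
})

test_that("mirroring the instance mirrors the predictions", {
  d <- liveInstance(seed = 8L)
  dm <- d
  dm@seqFeatures <- -d@seqFeatures
  dm@atomicFeatures <- -d@atomicFeatures
  dm@label <- -d@label
  dm@hiddenLabel <- -d@hiddenLabel
  for (m in c("tsvm", "attsvm")) {
    f1 <- predictedLabels(fitATTSVM(d, mode = m))
    f2 <- predictedLabels(fitATTSVM(dm, mode = m))
    expect_identical(unname(f2), unname(-f1))
  }
})

test_that("the class-mean transfer variant pins imputations to the means", {
  d <- simulateContactData(nTrain = 50L, nTest = 30L,
                           atomicSeparation = 1.5, seed = 4L)
  fit <- fitATTSVM(d, mode = "attsvm", transfer = "classmean")
  imp <- fit@transfer$imputed
  wl <- predictedLabels(fit)
  expect_true(all(apply(imp[wl == 1L, , drop = FALSE], 1L,
                        function(r) isTRUE(all.equal(
                          unname(r), unname(fit@transfer$posA))))))
})

test_that("training history is well-formed and iterations increase", {
  d <- liveInstance()
  h <- trainHistory(fitATTSVM(d, mode = "tsvm"))
  expect_true(all(diff(h$iteration) == 1L))
  expect_true(all(h$objective >= 0))
  expect_true(all(h$cPlus <= 1 + 1e-12))
})
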