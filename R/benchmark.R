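#' Evaluate a fitted run against retained truth
#'
#' Scores the final pool labels of a fit against the dataset's
#' privately retained true labels, excluding every example whose label
#' was revealed by the oracle during training.
#'
#' @param fit an [ATTSVMFit-class]
#' @param d the [ContactDataset-class] the fit was trained on.
#' @return an [evalReport()] list.
#' @export
evaluateFit <- function(fit, d) {
  pred <- predictedLabels(fit)
  ids <- names(pred)
  truth <- hiddenLabels(d)[ids]
  eligible <- isEvalEligible(d)[ids] & !ids %in% queriedIds(fit) &
    !is.na(truth)
  evalReport(pred, truth, scores = decisionValues(fit),
             eligible = eligible)
}

#' Three-way benchmark over paired seeds
#'
#' Generates one synthetic dataset per seed ([simulateContactData()])
#' and fits each requested method to the same data, so that per-seed
#' differences are paired.  Optionally adds the global-class-mean
#' ablation arm of the transfer update.
#'
#' @param seeds integer vector of generator seeds.
#' @param methods subset of `c("svm", "tsvm", "attsvm")`.
#' @param includeClassMean also run `attsvm` with
#'   `transfer = "classmean"` (reported as method `"attsvm_classmean"`).
#' @param genArgs list of arguments passed to [simulateContactData()].
#' @param fitArgs list of arguments passed to [fitATTSVM()].
#' @return list with `reports` (per-method data.frame of precision,
#'   recall, f1, roc by seed) and `histories` (per-method list of
#'   training histories).
#' @export
runBenchmark <- function(seeds = 1:10,
                         methods = c("svm", "tsvm", "attsvm"),
                         includeClassMean = FALSE,
                         genArgs = list(), fitArgs = list()) {
  arms <- c(methods, if (includeClassMean) "attsvm_classmean")
  reports <- setNames(
    rep(list(data.frame(precision = numeric(0), recall = numeric(0),
                        f1 = numeric(0), roc = numeric(0))), length(arms)),
    arms)
  histories <- setNames(rep(list(list()), length(arms)), arms)
  for (s in seeds) {
    d <- do.call(simulateContactData, c(list(seed = s), genArgs))
    for (arm in arms) {
      fa <- c(list(d = d, seed = s), fitArgs)
      fa$mode <- if (arm == "attsvm_classmean") "attsvm" else arm
      if (arm == "attsvm_classmean") fa$transfer <- "classmean"
      fit <- do.call(fitATTSVM, fa)
      r <- evaluateFit(fit, d)
      reports[[arm]] <- rbind(reports[[arm]], data.frame(
        precision = r$precision, recall = r$recall, f1 = r$f1,
        roc = r$roc))
      histories[[arm]][[as.character(s)]] <- trainHistory(fit)
    }
  }
  list(reports = reports, histories = histories)
}
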