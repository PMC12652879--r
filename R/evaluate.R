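#' Confusion counts over evaluation-eligible examples
#'
#' Tallies TP/FP/TN/FN with the contact class (+1) as positive.
#' Examples whose true label was revealed by the oracle must be
#' excluded; pass their eligibility flags.
#'
#' @param pred predicted labels (+1/-1).
#' @param truth true labels (+1/-1).
#' @param eligible logical flags; ineligible examples are dropped from
#'   every count.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @examples
#' confusionCounts(c(1, 1, -1, -1), c(1, -1, -1, 1))
#' @export
confusionCounts <- function(pred, truth, eligible = NULL) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (is.null(eligible)) eligible <- rep(TRUE, length(pred))
  if (length(eligible) != length(pred))
    stop("eligibility flags must match length")
  p <- pred[eligible]
  t <- truth[eligible]
  c(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == -1),
    TN = sum(p == -1 & t == -1), FN = sum(p == -1 & t == 1))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`; any 0/0 is defined as 0 so that degenerate
#' runs are comparable (flagged via the `degenerate` attribute).
#'
#' @param cc named counts as from [confusionCounts()].
#' @return named numeric `c(precision, recall, f1)`.
#' @export
prf1 <- function(cc) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  out <- c(precision = safe(cc[["TP"]], cc[["TP"]] + cc[["FP"]]),
           recall = safe(cc[["TP"]], cc[["TP"]] + cc[["FN"]]),
           f1 = safe(2 * cc[["TP"]], 2 * cc[["TP"]] + cc[["FP"]] + cc[["FN"]]))
  attr(out, "degenerate") <- (cc[["TP"]] + cc[["FP"]] == 0) ||
    (cc[["TP"]] + cc[["FN"]] == 0)
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC of the true-positive rate against the false-positive
#' rate as the score threshold slides, computed by the rank
#' (Mann-Whitney) formulation; tied scores follow the midpoint
#' convention.  1 for a perfect scorer, 0.5 for a random one.
#'
#' @param scores numeric prediction scores (larger = more contact-like).
#' @param truth true labels (+1/-1).
#' @return numeric in `[0, 1]`.
#' @export
rocScore <- function(scores, truth) {
  pos <- truth == 1
  neg <- truth == -1
  n1 <- as.numeric(sum(pos))
  n0 <- as.numeric(sum(neg))
  if (n1 == 0 || n0 == 0)
    stop("ROC undefined: both classes must be present")
  r <- rank(scores[pos | neg], ties.method = "average")
  (sum(r[truth[pos | neg] == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report
#'
#' @param pred predicted labels (+1/-1), optionally named.
#' @param truth true labels.
#' @param scores optional prediction scores for the ROC.
#' @param eligible eligibility flags (see [confusionCounts()]).
#' @return list with `counts`, `precision`, `recall`, `f1`, `roc`
#'   (`NA` when scores are missing) and `nExcluded`.
#' @export
evalReport <- function(pred, truth, scores = NULL, eligible = NULL) {
  if (is.null(eligible)) eligible <- rep(TRUE, length(pred))
  cc <- confusionCounts(pred, truth, eligible)
  pr <- prf1(cc)
  roc <- if (is.null(scores)) NA_real_
         else rocScore(scores[eligible], truth[eligible])
  list(counts = cc, precision = pr[["precision"]],
       recall = pr[["recall"]], f1 = pr[["f1"]], roc = roc,
       nExcluded = sum(!eligible))
}

#' Compare methods across seeds
#'
#' Summarizes per-seed evaluation reports as mean +/- standard
#' deviation per metric and method, plus paired mean differences
#' between every pair of methods (the headline comparison when the
#' same seeds were used throughout).
#'
#' @param reports named list (one element per method) of data.frames
#'   with one row per seed and metric columns (e.g. precision, recall,
#'   f1, roc).
#' @return list with data.frames `summary` and `differences`.
#' @export
compareRuns <- function(reports) {
  ns <- vapply(reports, nrow, 0L)
  if (length(unique(ns)) != 1L)
    stop("all methods must cover the same seed list")
  metrics <- Reduce(intersect, lapply(reports, names))
  summary <- do.call(rbind, lapply(names(reports), function(m) {
    df <- reports[[m]]
    data.frame(method = m, metric = metrics,
               mean = vapply(metrics, function(k) mean(df[[k]]), 0),
               sd = vapply(metrics, function(k)
                 if (nrow(df) < 2L) 0 else sd(df[[k]]), 0),
               row.names = NULL)
  }))
  pairs <- if (length(reports) > 1L) utils::combn(names(reports), 2L)
           else matrix(character(0), 2L, 0L)
  differences <- do.call(rbind, c(list(
    data.frame(comparison = character(0), metric = character(0),
               meanDiff = numeric(0))),
    lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      data.frame(comparison = paste0(a, "-", b), metric = metrics,
                 meanDiff = vapply(metrics, function(k)
                   mean(reports[[a]][[k]] - reports[[b]][[k]]), 0),
                 row.names = NULL)
    })))
  list(summary = summary, differences = differences)
}

#' Write a contact map as text
#'
#' One row per evaluable residue pair (`i j score label`, i < j), and
#' optionally a dense L x L score matrix alongside.
#'
#' @param cm a [ContactMap-class]
#' @param file output path for the pair list.
#' @param denseFile optional path for the dense score matrix.
#' @return `file`, invisibly.
#' @export
writeContactMap <- function(cm, file, denseFile = NULL) {
  L <- nrow(cm@labels)
  idx <- which(upper.tri(cm@labels) & !is.na(cm@labels), arr.ind = TRUE)
  tab <- data.frame(i = idx[, 1L], j = idx[, 2L],
                    score = cm@scores[idx], label = cm@labels[idx])
  tab <- tab[order(tab$i, tab$j), ]
  atomicWrite(tab, file)
  if (!is.null(denseFile)) {
    tmp <- paste0(denseFile, ".tmp")
    write.table(cm@scores, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    file.rename(tmp, denseFile)
  }
  invisible(file)
}

#' @export
setMethod("show", "ContactMap", function(object) {
  lv <- object@labels[upper.tri(object@labels)]
  cat(sprintf(
    "ContactMap %s: L = %d, %d contacts / %d non-contacts (minSep %d, cutoff %.2f A)\n",
    object@proteinId, nrow(object@labels),
    sum(lv == 1L, na.rm = TRUE), sum(lv == -1L, na.rm = TRUE),
    object@minSep, object@cutoff))
  invisible(NULL)
})
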