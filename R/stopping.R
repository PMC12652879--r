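#' Detect the validation-F1 peak
#'
#' Declares the peak of a monitored F1 series once `patience`
#' consecutive values strictly below the running maximum have been
#' observed at the end of the series; ties take the earliest maximum.
#' Appending further values below the declared peak never changes the
#' result.
#'
#' @param f1Series numeric vector of validation F1 values in order of
#'   iteration.
#' @param patience number of consecutive below-peak values required
#'   (>= 1).
#' @return integer index (1-based) of the peak, or `NA` if the peak has
#'   not been captured yet.
#' @examples
#' detectPeak(c(0.5, 0.6, 0.7, 0.65, 0.6), patience = 2)   # 3
#' detectPeak(c(0.5, 0.6, 0.7), patience = 2)              # NA (not yet)
#' @export
detectPeak <- function(f1Series, patience = 2L) {
  stopifnot(patience >= 1L)
  if (!length(f1Series)) return(NA_integer_)
  best <- -Inf
  bestIdx <- NA_integer_
  below <- 0L
  for (t in seq_along(f1Series)) {
    if (f1Series[t] > best) {
      best <- f1Series[t]
      bestIdx <- t
      below <- 0L
    } else if (f1Series[t] < best) {
      below <- below + 1L
    } else {
      below <- 0L                    # plateau at the maximum
    }
    if (below >= patience) return(bestIdx)
  }
  NA_integer_
}

#' Select active-learning queries from the pool
#'
#' Ranks pool examples by the decision function and returns the `k` ids
#' to query.  The default `"margin"` ranking selects the smallest
#' `|f|` -- the most uncertain examples, closest to the hyperplane --
#' with distance ties broken by ascending id.  `"descending"` is the
#' literal variant that takes the largest signed `f` first.
#'
#' @param decision named numeric vector of decision values, or unnamed
#'   with `ids` supplied.
#' @param ids example ids (defaults to `names(decision)`).
#' @param k number of queries (0 <= k <= pool size).
#' @param ranking `"margin"` or `"descending"`.
#' @return character vector of `k` ids in query order.
#' @examples
#' selectQueries(c(A = 0.1, B = -0.05, C = 2.0, D = -1.5), k = 2)
#' @export
selectQueries <- function(decision, ids = names(decision), k,
                          ranking = c("margin", "descending")) {
  ranking <- match.arg(ranking)
  if (k > length(decision)) stop("k exceeds pool size")
  if (k == 0L || !length(decision)) return(character(0))
  ord <- if (ranking == "margin") order(abs(decision), ids)
         else order(-decision, ids)
  ids[ord][seq_len(k)]
}

#' Reveal true labels for queried examples
#'
#' Moves the queried examples from the unlabeled pool to the labeled
#' set: each receives its true label from the oracle and is flagged
#' evaluation-ineligible.  The measured atomic block stays absent (the
#' oracle reveals labels, not structures); during training the engine
#' keeps the example's current imputed block.
#'
#' @param d a [ContactDataset-class]
#' @param ids ids currently in the unlabeled pool.
#' @param oracle function mapping ids to +1/-1 labels; defaults to the
#'   dataset's privately retained truth.
#' @param budget remaining query budget; if smaller than `length(ids)`
#'   the call is refused (no-op with a warning).
#' @return list with the updated `dataset` and the remaining `budget`.
#' @export
applyOracle <- function(d, ids, oracle = NULL, budget = Inf) {
  idx <- match(ids, d@ids)
  if (anyNA(idx)) stop("unknown example id(s)")
  if (any(d@labeled[idx]))
    stop("cannot query an already-labeled example: ",
         paste(ids[d@labeled[idx]], collapse = ", "))
  if (length(ids) > budget) {
    warning("oracle budget exhausted; query refused", call. = FALSE)
    return(list(dataset = d, budget = budget))
  }
  if (is.null(oracle)) {
    truth <- hiddenLabels(d)
    oracle <- function(ii) truth[ii]
  }
  lab <- as.integer(oracle(ids))
  if (any(is.na(lab)) || !all(lab %in% c(-1L, 1L)))
    stop("oracle returned invalid labels")
  d@label[idx] <- lab
  d@labeled[idx] <- TRUE
  d@evalEligible[idx] <- FALSE
  validObject(d)
  list(dataset = d, budget = budget - length(ids))
}
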