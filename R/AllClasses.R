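#' ContactDataset: residue-pair examples for transductive learning
#'
#' Container for a two-block feature table over residue pairs.  Every
#' example carries a sequence-feature block; labeled (training) examples
#' additionally carry an atomic-feature block and a class label
#' (+1 contact / -1 non-contact).  Unlabeled examples have a structurally
#' absent atomic block (all-`NA` row) and an unknown label.  Hidden truth
#' (labels and, for synthetic data, atomic blocks) may be retained
#' privately for the active-learning oracle and for evaluation; it is
#' never consulted by the learner itself.
#'
#' @slot ids character, unique example identifiers
#'   (convention `"<protein>:<i>-<j>"` with 1-based indices, i < j).
#' @slot seqFeatures numeric matrix, one row per example.
#' @slot atomicFeatures numeric matrix; a row is either fully observed or
#'   fully `NA` (absent).
#' @slot label integer, +1 / -1 for labeled rows, `NA` otherwise.
#' @slot labeled logical, `TRUE` for training rows.
#' @slot evalEligible logical; set to `FALSE` once an example's true
#'   label has been revealed by the oracle, excluding it from evaluation.
#' @slot hiddenLabel integer, privately retained truth (`NA` if unknown).
#' @slot hiddenAtomic numeric matrix of privately retained atomic truth,
#'   or a 0-row matrix when not available.
#'
#' @seealso [contactDataset()], [validateDataset()], [splitValidation()]
#' @export
setClass("ContactDataset",
  representation(
    ids = "character",
    seqFeatures = "matrix",
    atomicFeatures = "matrix",
    label = "integer",
    labeled = "logical",
    evalEligible = "logical",
    hiddenLabel = "integer",
    hiddenAtomic = "matrix"
  )
)

setValidity("ContactDataset", function(object) {
  n <- length(object@ids)
  msg <- character()
  if (nrow(object@seqFeatures) != n)
    msg <- c(msg, "seqFeatures row count disagrees with ids")
  if (nrow(object@atomicFeatures) != n)
    msg <- c(msg, "atomicFeatures row count disagrees with ids")
  for (s in c("label", "labeled", "evalEligible", "hiddenLabel"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, paste(s, "length disagrees with ids"))
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicated example ids")
  if (ncol(object@seqFeatures) < 1L || ncol(object@atomicFeatures) < 1L)
    msg <- c(msg, "feature blocks must have at least one column")
  if (nrow(object@hiddenAtomic) != 0L &&
      (nrow(object@hiddenAtomic) != n ||
       ncol(object@hiddenAtomic) != ncol(object@atomicFeatures)))
    msg <- c(msg, "hiddenAtomic dimensions disagree")
  # rows of the atomic block are all-observed or all-absent, never mixed
  if (n > 0L) {
    nNA <- rowSums(is.na(object@atomicFeatures))
    if (any(nNA > 0L & nNA < ncol(object@atomicFeatures)))
      msg <- c(msg, "atomic rows must be fully observed or fully absent")
  }
  if (length(msg)) msg else TRUE
})

#' MarginModel: a fitted separating hyperplane with slack state
#'
#' Linear decision rule `f(x) = w . x + b` together with the per-example
#' hinge slacks of the instance it was fitted on and the three-way
#' penalty state (labeled cost `C`, unlabeled costs `cPlus`/`cMinus`
#' with target cap `cStar`).
#'
#' @slot w numeric weight vector (named by feature).
#' @slot b numeric(1) bias.
#' @slot slackLabeled,slackUnlabeled named non-negative numerics.
#' @slot unlabeledLabels named integer, the working labels under which
#'   the unlabeled slacks were computed.
#' @slot penalties list with elements `C`, `cPlus`, `cMinus`, `cStar`.
#' @seealso [solveSoftMargin()], [decisionValue()], [svmObjective()]
#' @export
setClass("MarginModel",
  representation(
    w = "numeric", b = "numeric",
    slackLabeled = "numeric", slackUnlabeled = "numeric",
    unlabeledLabels = "integer", penalties = "list"
  )
)

setValidity("MarginModel", function(object) {
  msg <- character()
  if (length(object@b) != 1L) msg <- c(msg, "b must be scalar")
  if (any(object@slackLabeled < -1e-12) || any(object@slackUnlabeled < -1e-12))
    msg <- c(msg, "slacks must be non-negative")
  p <- object@penalties
  need <- c("C", "cPlus", "cMinus", "cStar")
  if (!all(need %in% names(p))) {
    msg <- c(msg, "penalties must contain C, cPlus, cMinus, cStar")
  } else {
    if (any(unlist(p[need]) <= 0)) msg <- c(msg, "penalties must be positive")
    if (p$cPlus > p$cStar + 1e-12 || p$cMinus > p$cStar + 1e-12)
      msg <- c(msg, "cPlus and cMinus must not exceed cStar")
  }
  if (length(object@slackUnlabeled) != length(object@unlabeledLabels))
    msg <- c(msg, "unlabeledLabels length disagrees with slackUnlabeled")
  if (length(msg)) msg else TRUE
})

#' ATTSVMFit: result of a transductive training run
#'
#' @slot model the final (or peak-restored) [MarginModel-class].
#' @slot mode `"svm"`, `"tsvm"` or `"attsvm"`.
#' @slot workingLabels named integer, final labels of the unlabeled pool.
#' @slot decision named numeric, final decision values of the pool.
#' @slot history per-iteration data.frame (iteration, cPlus, cMinus,
#'   nSwaps, objective, valF1, nQueries, testF1).
#' @slot transfer list: `posA`, `negA`, `imputed` matrix, `kKnn`.
#' @slot queried character ids revealed by the active-learning oracle.
#' @slot scaling list of centering/scale vectors used to standardize.
#' @slot stoppedAt integer iteration at which training stopped
#'   (`NA` when run to the penalty cap).
#' @slot config list echoing the hyperparameters of the run.
#' @export
setClass("ATTSVMFit",
  representation(
    model = "MarginModel", mode = "character",
    workingLabels = "integer", decision = "numeric",
    history = "data.frame", transfer = "list", queried = "character",
    scaling = "list", stoppedAt = "integer", config = "list"
  )
)

#' CouplingStack: per-protein coupling-score matrices
#'
#' Four L-by-L symmetric score matrices for one protein, one per
#' direct-coupling-analysis method.
#'
#' @slot proteinId character(1).
#' @slot matrices list of four numeric L x L matrices.
#' @seealso [readCouplingStack()], [pairSeqFeatures()]
#' @export
setClass("CouplingStack",
  representation(proteinId = "character", matrices = "list"))

setValidity("CouplingStack", function(object) {
  m <- object@matrices
  if (length(m) != 4L) return("exactly four coupling matrices required")
  L <- nrow(m[[1L]])
  for (i in seq_along(m)) {
    if (!is.matrix(m[[i]]) || !is.numeric(m[[i]]))
      return("coupling matrices must be numeric matrices")
    if (nrow(m[[i]]) != L || ncol(m[[i]]) != L)
      return("all coupling matrices must be square and share L")
    if (!all(is.finite(m[[i]])))
      return("coupling scores must be finite")
  }
  TRUE
})

#' StructureModel: residue-level heavy-atom coordinates with helices
#'
#' @slot proteinId character(1).
#' @slot coords list indexed by residue number: numeric matrix of
#'   heavy-atom coordinates (Angstrom), one row per atom.
#' @slot ca numeric L x 3 matrix of C-alpha coordinates (`NA` rows for
#'   residues without a C-alpha record).
#' @slot helices data.frame with columns `start`, `end`
#'   (1-based residue indices, inclusive).
#' @seealso [readStructureModel()], [pairAtomicFeatures()],
#'   [labelContacts()]
#' @export
setClass("StructureModel",
  representation(proteinId = "character", coords = "list",
                 ca = "matrix", helices = "data.frame"))

setValidity("StructureModel", function(object) {
  L <- length(object@coords)
  msg <- character()
  if (nrow(object@ca) != L) msg <- c(msg, "ca row count disagrees")
  nat <- vapply(object@coords, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  if (!all(c("start", "end") %in% names(object@helices)))
    msg <- c(msg, "helices needs start and end columns")
  else if (nrow(object@helices) &&
           any(object@helices$start > object@helices$end))
    msg <- c(msg, "helix start must not exceed end")
  if (length(msg)) msg else TRUE
})

#' ComponentRanking: principal components ranked by predictive power
#'
#' A fitted centering/standardization and rotation together with a
#' per-component discriminative score (default: |AUC - 0.5| of the
#' component's projection against the training labels) and the indices
#' of the retained components, in rank order.
#'
#' @slot center,scale numeric vectors of the standardization.
#' @slot rotation numeric matrix (input dim x n components).
#' @slot scores numeric, non-negative predictive-power scores.
#' @slot selected integer, retained component indices in rank order.
#' @slot scorer character(1), `"auc"` or `"svm"`.
#' @seealso [fitComponentRanking()], [applyComponentRanking()]
#' @export
setClass("ComponentRanking",
  representation(center = "numeric", scale = "numeric",
                 rotation = "matrix", scores = "numeric",
                 selected = "integer", scorer = "character"))

setValidity("ComponentRanking", function(object) {
  msg <- character()
  if (any(object@scores < 0)) msg <- c(msg, "scores must be non-negative")
  if (length(object@selected) > ncol(object@rotation))
    msg <- c(msg, "selected count exceeds component count")
  if (length(msg)) msg else TRUE
})

#' ContactMap: per-protein contact labels and scores
#'
#' Symmetric square map over residue indices.  Entries within the
#' minimum sequence separation are `NA` (excluded from both classes);
#' remaining entries are +1 (contact) or -1 (non-contact).  A parallel
#' score matrix may hold prediction scores.
#'
#' @slot proteinId character(1).
#' @slot labels integer L x L matrix (+1/-1/NA).
#' @slot scores numeric L x L matrix (may be all-NA for ground truth).
#' @slot minSep integer minimum sequence separation.
#' @slot cutoff numeric heavy-atom distance cutoff in Angstrom.
#' @seealso [labelContacts()], [writeContactMap()]
#' @export
setClass("ContactMap",
  representation(proteinId = "character", labels = "matrix",
                 scores = "matrix", minSep = "integer", cutoff = "numeric"))

setValidity("ContactMap", function(object) {
  L <- nrow(object@labels)
  msg <- character()
  if (ncol(object@labels) != L) msg <- c(msg, "labels must be square")
  if (!identical(dim(object@scores), dim(object@labels)))
    msg <- c(msg, "scores dimensions disagree with labels")
  lv <- object@labels[!is.na(object@labels)]
  if (length(lv) && !all(lv %in% c(-1L, 1L)))
    msg <- c(msg, "labels must be +1, -1 or NA")
  if (!isTRUE(all.equal(object@labels, t(object@labels))))
    msg <- c(msg, "labels must be symmetric")
  if (length(msg)) msg else TRUE
})
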