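#' Construct a ContactDataset
#'
#' Assembles labeled and unlabeled residue-pair examples into a
#' [ContactDataset-class].  Labels are encoded internally as +1
#' (contact) / -1 (non-contact); an absent atomic block is an all-`NA`
#' row, a structural state distinct from a measurement gap.
#'
#' @param seqFeatures numeric matrix of sequence features, one row per
#'   example.
#' @param atomicFeatures numeric matrix of atomic features; rows for
#'   unlabeled examples should be `NA`.  If `NULL`, all rows are absent
#'   (`nAtomic` columns of `NA`).
#' @param label integer/numeric vector of +1/-1 labels (`NA` unknown).
#' @param labeled logical vector; defaults to "label known and atomic
#'   present".
#' @param ids character identifiers; defaults to `ex0001, ...`.
#' @param evalEligible logical; defaults to `TRUE` everywhere.
#' @param hiddenLabel privately retained true labels (`NA` if unknown);
#'   used only by the oracle and by evaluation helpers.
#' @param hiddenAtomic privately retained true atomic blocks.
#' @param nAtomic atomic block width when `atomicFeatures` is `NULL`.
#' @return a [ContactDataset-class]
#' @examples
#' d <- contactDataset(matrix(rnorm(20), 10), label = rep(c(1, -1), 5),
#'                     atomicFeatures = matrix(rnorm(20), 10))
#' nExamples(d)
#' @export
contactDataset <- function(seqFeatures, atomicFeatures = NULL, label = NULL,
                           labeled = NULL, ids = NULL, evalEligible = NULL,
                           hiddenLabel = NULL, hiddenAtomic = NULL,
                           nAtomic = 2L) {
  seqFeatures <- as.matrix(seqFeatures)
  n <- nrow(seqFeatures)
  # canonical column names keep the on-disk format round-trippable
  colnames(seqFeatures) <- paste0("s", seq_len(ncol(seqFeatures)))
  if (is.null(atomicFeatures))
    atomicFeatures <- matrix(NA_real_, n, nAtomic)
  atomicFeatures <- as.matrix(atomicFeatures)
  colnames(atomicFeatures) <- paste0("a", seq_len(ncol(atomicFeatures)))
  if (is.null(label)) label <- rep(NA_integer_, n)
  label <- as.integer(label)
  if (is.null(labeled))
    labeled <- !is.na(label) & rowSums(is.na(atomicFeatures)) == 0L
  if (is.null(ids)) ids <- sprintf("ex%04d", seq_len(n))
  if (is.null(evalEligible)) evalEligible <- rep(TRUE, n)
  if (is.null(hiddenLabel)) hiddenLabel <- rep(NA_integer_, n)
  if (is.null(hiddenAtomic))
    hiddenAtomic <- matrix(numeric(0), 0L, ncol(atomicFeatures))
  new("ContactDataset", ids = as.character(ids), seqFeatures = seqFeatures,
      atomicFeatures = atomicFeatures, label = label,
      labeled = as.logical(labeled), evalEligible = as.logical(evalEligible),
      hiddenLabel = as.integer(hiddenLabel),
      hiddenAtomic = as.matrix(hiddenAtomic))
}

#' @describeIn contactDataset number of examples
#' @param d a [ContactDataset-class]
#' @export
nExamples <- function(d) length(d@ids)

#' Accessors for ContactDataset
#'
#' @param d a [ContactDataset-class]
#' @return `exampleIds`: character; `seqFeatures`/`atomicFeatures`:
#'   matrices; `exampleLabels`/`hiddenLabels`: integer (+1/-1/`NA`);
#'   `isLabeled`/`isEvalEligible`: logical; `featureSchema`: named
#'   integer with elements `nSeq`, `nAtomic`.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
exampleIds <- function(d) d@ids
#' @rdname dataset-accessors
#' @export
seqFeatures <- function(d) d@seqFeatures
#' @rdname dataset-accessors
#' @export
atomicFeatures <- function(d) d@atomicFeatures
#' @rdname dataset-accessors
#' @export
exampleLabels <- function(d) setNames(d@label, d@ids)
#' @rdname dataset-accessors
#' @export
hiddenLabels <- function(d) setNames(d@hiddenLabel, d@ids)
#' @rdname dataset-accessors
#' @export
isLabeled <- function(d) setNames(d@labeled, d@ids)
#' @rdname dataset-accessors
#' @export
isEvalEligible <- function(d) setNames(d@evalEligible, d@ids)
#' @rdname dataset-accessors
#' @export
featureSchema <- function(d)
  c(nSeq = ncol(d@seqFeatures), nAtomic = ncol(d@atomicFeatures))

#' @export
setMethod("show", "ContactDataset", function(object) {
  sch <- featureSchema(object)
  cat(sprintf(
    "ContactDataset: %d examples (%d labeled, %d unlabeled), %d+%d features\n",
    nExamples(object), sum(object@labeled), sum(!object@labeled),
    sch[["nSeq"]], sch[["nAtomic"]]))
  if (sum(object@labeled))
    cat(sprintf("  labeled classes: %d contact / %d non-contact\n",
                sum(object@label == 1L & object@labeled, na.rm = TRUE),
                sum(object@label == -1L & object@labeled, na.rm = TRUE)))
  if (any(!object@evalEligible))
    cat(sprintf("  %d example(s) oracle-revealed (evaluation-ineligible)\n",
                sum(!object@evalEligible)))
  invisible(NULL)
})

#' @export
setMethod("[", "ContactDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  hid <- if (nrow(x@hiddenAtomic)) x@hiddenAtomic[i, , drop = FALSE]
         else x@hiddenAtomic
  new("ContactDataset", ids = x@ids[i],
      seqFeatures = x@seqFeatures[i, , drop = FALSE],
      atomicFeatures = x@atomicFeatures[i, , drop = FALSE],
      label = x@label[i], labeled = x@labeled[i],
      evalEligible = x@evalEligible[i], hiddenLabel = x@hiddenLabel[i],
      hiddenAtomic = hid)
})

#' Check the semantic invariants of a dataset
#'
#' Structural consistency (dimensions, types) is enforced by the class
#' validity method; this reports rule violations a structurally valid
#' object can still exhibit.  An empty return value means the dataset is
#' ready for training.
#'
#' @param d a [ContactDataset-class]
#' @return character vector of violations, each naming the offending
#'   example id (or `<dataset>`) and the broken rule; empty if none.
#' @examples
#' d <- contactDataset(matrix(rnorm(8), 4), label = c(1, 1, -1, -1),
#'                     atomicFeatures = matrix(rnorm(8), 4))
#' validateDataset(d)   # character(0)
#' @export
validateDataset <- function(d) {
  v <- character()
  bad <- which(!is.finite(d@seqFeatures), arr.ind = TRUE)
  for (r in unique(bad[, 1L]))
    v <- c(v, paste0(d@ids[r], ": non-finite sequence feature"))
  obs <- rowSums(is.na(d@atomicFeatures)) == 0L
  inf <- rowSums(!is.finite(d@atomicFeatures)) > 0L & obs
  for (r in which(inf))
    v <- c(v, paste0(d@ids[r], ": non-finite atomic feature"))
  # oracle-revealed examples (evalEligible FALSE) legitimately lack a
  # measured atomic block: the oracle reveals labels, not structures
  for (r in which(d@labeled & !obs & d@evalEligible))
    v <- c(v, paste0(d@ids[r], ": labeled example missing atomic block"))
  for (r in which(d@labeled & is.na(d@label)))
    v <- c(v, paste0(d@ids[r], ": labeled example without label"))
  for (r in which(!is.na(d@label) & !d@label %in% c(-1L, 1L)))
    v <- c(v, paste0(d@ids[r], ": label must be +1 or -1"))
  for (r in which(!d@labeled & !is.na(d@label)))
    v <- c(v, paste0(d@ids[r], ": unlabeled example carries a label"))
  lab <- d@label[d@labeled]
  if (sum(d@labeled) > 0L) {
    if (!any(lab == 1L, na.rm = TRUE))
      v <- c(v, "<dataset>: labeled set missing class +1")
    if (!any(lab == -1L, na.rm = TRUE))
      v <- c(v, "<dataset>: labeled set missing class -1")
  } else v <- c(v, "<dataset>: no labeled examples")
  v
}

#' Split off a validation set from the labeled examples
#'
#' Samples `nVal` labeled examples without replacement, stratified by
#' class so that a small draw cannot miss a class, and returns them as a
#' separate dataset.  Deterministic for a fixed seed.
#'
#' @param d a [ContactDataset-class]
#' @param nVal number of validation examples (default 20).
#' @param seed integer seed for the draw.
#' @return list with elements `train` and `validation`, both
#'   [ContactDataset-class] objects.  `train` keeps all unlabeled
#'   examples.
#' @export
splitValidation <- function(d, nVal = 20L, seed = 1L) {
  labIdx <- which(d@labeled)
  if (nVal >= length(labIdx))
    stop("nVal must be smaller than the labeled set (", length(labIdx), ")")
  if (nVal == 0L)
    return(list(train = d, validation = d[integer(0)]))
  pos <- labIdx[d@label[labIdx] == 1L]
  neg <- labIdx[d@label[labIdx] == -1L]
  nPos <- round(nVal * length(pos) / length(labIdx))
  nPos <- max(min(nPos, nVal - 1L, length(pos) - 1L), 1L)
  nNeg <- nVal - nPos
  if (nNeg >= length(neg))
    stop("nVal too large to keep both classes in the training part")
  valIdx <- sort(c(
    withSeed(seed, sample(pos, nPos)),
    withSeed(seed + 1L, sample(neg, nNeg))))
  list(train = d[setdiff(seq_len(nExamples(d)), valIdx)],
       validation = d[valIdx])
}

# evaluate expr under a temporary RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
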