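#' Read and write residue-pair feature tables
#'
#' The on-disk format is a tab-separated table with header
#' `id  s1..s<n>  a1..a<m>  label`, one residue pair per row.  An absent
#' atomic block is written as empty fields (never `NaN`-as-data: the
#' absence is structural, so generic imputers must not silently apply).
#' Labels are written as `contact`/`noncontact`; on reading, the strings
#' `contact`/`noncontact`/`non-contact` and the integers `1`/`0` (or
#' `+1`/`-1`) are all accepted, and an empty field means unknown.
#'
#' @param d a [ContactDataset-class]
#' @param file path of the tab-separated table.
#' @param hidden if `TRUE`, `writeFeatureTable` writes the privately
#'   retained truth labels instead of the public ones (used for the
#'   oracle/truth table of a simulation).
#' @return `readFeatureTable`: a [ContactDataset-class];
#'   `writeFeatureTable`: the file path, invisibly.
#' @examples
#' d <- contactDataset(matrix(rnorm(8), 4), label = c(1, 1, -1, -1),
#'                     atomicFeatures = matrix(rnorm(8), 4))
#' f <- tempfile(fileext = ".tsv")
#' writeFeatureTable(d, f)
#' d2 <- readFeatureTable(f)
#' stopifnot(identical(exampleLabels(d), exampleLabels(d2)))
#' @export
writeFeatureTable <- function(d, file, hidden = FALSE) {
  lab <- if (hidden) d@hiddenLabel else d@label
  labStr <- ifelse(is.na(lab), "",
                   ifelse(lab == 1L, "contact", "noncontact"))
  fmtNum <- function(m) {
    out <- format(m, digits = 17, trim = TRUE)
    out[is.na(m)] <- ""
    out
  }
  tab <- data.frame(id = d@ids, fmtNum(d@seqFeatures),
                    fmtNum(d@atomicFeatures), label = labStr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  atomicWrite(tab, file)
  invisible(file)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(file) {
  tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!"id" %in% names(tab) || !"label" %in% names(tab))
    stop("feature table needs 'id' and 'label' columns")
  sCols <- grep("^s[0-9]+$", names(tab), value = TRUE)
  aCols <- grep("^a[0-9]+$", names(tab), value = TRUE)
  if (!length(sCols)) stop("no sequence feature columns (s1, s2, ...)")
  if (!length(aCols)) stop("no atomic feature columns (a1, a2, ...)")
  num <- function(cols) {
    m <- vapply(tab[cols], function(x) suppressWarnings(as.numeric(x)),
                numeric(nrow(tab)))
    matrix(m, nrow = nrow(tab), dimnames = list(NULL, cols))
  }
  contactDataset(seqFeatures = num(sCols), atomicFeatures = num(aCols),
                 label = parseLabels(tab$label), ids = tab$id)
}

parseLabels <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("contact", "1", "+1")] <- 1L
  out[x %in% c("noncontact", "non-contact", "0", "-1")] <- -1L
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad))
    stop("unrecognized label value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read/write a truth table (id, label)
#'
#' Two-column tab-separated file mapping example ids to their true
#' labels, used as the active-learning oracle and for evaluation.
#'
#' @param labels named integer vector (+1/-1), or a
#'   [ContactDataset-class] whose hidden labels are written.
#' @param file path.
#' @return `readTruthTable`: named integer vector.
#' @export
writeTruthTable <- function(labels, file) {
  if (is(labels, "ContactDataset"))
    labels <- hiddenLabels(labels)
  labels <- labels[!is.na(labels)]
  tab <- data.frame(id = names(labels),
                    label = ifelse(labels == 1L, "contact", "noncontact"))
  atomicWrite(tab, file)
  invisible(file)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE,
                    colClasses = "character")
  setNames(parseLabels(tab$label), tab$id)
}

#' Serialize a MarginModel to a flat key-value text file
#'
#' @param m a [MarginModel-class]
#' @param file path
#' @return `readModelState`: a [MarginModel-class] (slack maps are not
#'   serialized; they belong to the training instance, not the rule).
#' @export
writeModelState <- function(m, file) {
  kv <- c(
    sprintf("w%d=%.17g", seq_along(m@w), m@w),
    sprintf("b=%.17g", m@b),
    sprintf("C=%.17g", m@penalties$C),
    sprintf("cPlus=%.17g", m@penalties$cPlus),
    sprintf("cMinus=%.17g", m@penalties$cMinus),
    sprintf("cStar=%.17g", m@penalties$cStar))
  tmp <- paste0(file, ".tmp")
  writeLines(kv, tmp)
  file.rename(tmp, file)
  invisible(file)
}

#' @rdname writeModelState
#' @export
readModelState <- function(file) {
  kv <- strsplit(readLines(file), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x) as.numeric(x[2L]), 0),
                   vapply(kv, `[`, "", 1L))
  wIdx <- grep("^w[0-9]+$", names(vals))
  new("MarginModel", w = unname(vals[wIdx]), b = unname(vals[["b"]]),
      slackLabeled = numeric(0), slackUnlabeled = numeric(0),
      unlabeledLabels = integer(0),
      penalties = list(C = unname(vals[["C"]]),
                       cPlus = unname(vals[["cPlus"]]),
                       cMinus = unname(vals[["cMinus"]]),
                       cStar = unname(vals[["cStar"]])))
}

# write a data.frame as TSV atomically (temp-then-rename)
atomicWrite <- function(tab, file) {
  tmp <- paste0(file, ".tmp")
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, file)
  invisible(file)
}
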