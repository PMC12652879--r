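#' The deduplicated coupling-score offset pattern
#'
#' Expands the base offsets (0,0), (0,1), (0,3), (0,4), (1,0), (3,0),
#' (3,4), (4,0), (4,3), (4,4) by their four sign reflections
#' `(+x,+y), (+x,-y), (-x,-y), (-x,+y)` and removes duplicates while
#' preserving first occurrence: exactly 25 distinct relative positions
#' (1 from the origin, 2 from each axis offset, 4 from each diagonal).
#'
#' @return integer matrix with 25 rows and columns `dx`, `dy`.
#' @export
offsetPositions <- function() {
  base <- rbind(c(0, 0), c(0, 1), c(0, 3), c(0, 4), c(1, 0),
                c(3, 0), c(3, 4), c(4, 0), c(4, 3), c(4, 4))
  out <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    x <- base[i, 1L]; y <- base[i, 2L]
    rbind(c(x, y), c(x, -y), c(-x, -y), c(-x, y))
  }))
  out <- out[!duplicated(out), , drop = FALSE]
  dimnames(out) <- list(NULL, c("dx", "dy"))
  out
}

#' Construct / read a coupling-score stack
#'
#' Four L x L matrices of residue-residue coupling scores for one
#' protein, one per direct-coupling-analysis method, in a fixed method
#' order given by a manifest file (one matrix file path per line,
#' relative paths resolved against the manifest's directory).  Matrix
#' files are whitespace-delimited plain numeric text.
#'
#' @param proteinId character(1).
#' @param matrices list of four numeric L x L matrices.
#' @return a [CouplingStack-class]
#' @export
couplingStack <- function(proteinId, matrices) {
  matrices <- lapply(matrices, as.matrix)
  new("CouplingStack", proteinId = proteinId, matrices = matrices)
}

#' @rdname couplingStack
#' @param manifest path to the 4-line manifest file.
#' @export
readCouplingStack <- function(manifest, proteinId = NULL) {
  paths <- trimws(readLines(manifest))
  paths <- paths[nzchar(paths) & !startsWith(paths, "#")]
  if (length(paths) != 4L)
    stop("manifest must list exactly four matrix files")
  dir <- dirname(manifest)
  full <- ifelse(file.exists(paths), paths, file.path(dir, paths))
  mats <- lapply(full, function(p)
    as.matrix(read.table(p, header = FALSE)))
  mats <- lapply(mats, unname)
  if (is.null(proteinId))
    proteinId <- sub("\\.[^.]*$", "", basename(manifest))
  couplingStack(proteinId, mats)
}

#' Windowed coupling-score features of a residue pair
#'
#' For a pair `(i, j)` and each of the 25 deduplicated offset positions
#' ([offsetPositions()]), reads the coupling score of the four methods
#' (100 values, position-major); out-of-range positions contribute 0.
#' A moving window of length three along the paired diagonal then
#' concatenates the 100-vectors of `(i-1, j-1)`, `(i, j)` and
#' `(i+1, j+1)` -- edge pairs padded with zeros -- into 300 values.
#'
#' @param cs a [CouplingStack-class]
#' @param i,j residue indices in `[1, L]`.
#' @return numeric vector of length 300.
#' @export
pairSeqFeatures <- function(cs, i, j) {
  L <- nrow(cs@matrices[[1L]])
  if (i < 1L || i > L || j < 1L || j > L)
    stop("residue index out of [1, ", L, "]")
  off <- offsetPositions()
  block <- function(ci, cj) {
    if (ci < 1L || ci > L || cj < 1L || cj > L)
      return(numeric(100L))
    px <- ci + off[, 1L]
    py <- cj + off[, 2L]
    ok <- px >= 1L & px <= L & py >= 1L & py <= L
    vals <- matrix(0, nrow(off), 4L)
    for (m in 1:4)
      vals[ok, m] <- cs@matrices[[m]][cbind(px[ok], py[ok])]
    as.vector(t(vals))               # position-major, method inner
  }
  c(block(i - 1L, j - 1L), block(i, j), block(i + 1L, j + 1L))
}

#' Construct a structure model
#'
#' @param proteinId character(1).
#' @param coords list indexed by residue number (1..L): numeric matrix
#'   of heavy-atom coordinates, rows optionally named by atom name
#'   (side-chain detection uses names; unnamed atoms count as
#'   backbone-less).
#' @param ca L x 3 matrix of C-alpha coordinates (`NA` rows allowed).
#' @param helices data.frame with `start`/`end` residue indices.
#' @return a [StructureModel-class]
#' @export
structureModel <- function(proteinId, coords, ca, helices =
                             data.frame(start = integer(0),
                                        end = integer(0))) {
  new("StructureModel", proteinId = proteinId, coords = coords,
      ca = as.matrix(ca), helices = helices)
}

#' Read a structure model from a PDB file
#'
#' Heavy atoms are all non-hydrogen atom records; alternate locations
#' keep the highest-occupancy conformer; insertion codes are rejected.
#' Helix segments come from the file's HELIX records unless a 3-column
#' TSV (`protein`, `start`, `end`) is supplied.
#'
#' @param pdbFile path to a PDB file (or a `bio3d` pdb object).
#' @param helixFile optional helix-segment TSV.
#' @param chain chain identifier; defaults to the first chain present.
#' @return a [StructureModel-class]
#' @export
readStructureModel <- function(pdbFile, helixFile = NULL, chain = NULL) {
  pdb <- if (is.character(pdbFile))
    bio3d::read.pdb(pdbFile, rm.alt = FALSE) else pdbFile
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported; renumber the structure")
  heavy <- is.na(at$elesy) | !at$elesy %in% c("H", "D")
  at <- at[heavy, , drop = FALSE]
  # alternate locations: highest occupancy per (residue, atom name)
  key <- paste(at$resno, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ii)
    ii[which.max(occ[ii])]), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  L <- max(at$resno)
  coords <- vector("list", L)
  ca <- matrix(NA_real_, L, 3L)
  for (r in unique(at$resno)) {
    rows <- at[at$resno == r, , drop = FALSE]
    m <- as.matrix(rows[, c("x", "y", "z")])
    rownames(m) <- rows$elety
    coords[[r]] <- m
    if ("CA" %in% rows$elety)
      ca[r, ] <- m["CA", ]
  }
  helices <- if (!is.null(helixFile)) {
    h <- read.delim(helixFile, stringsAsFactors = FALSE)
    data.frame(start = as.integer(h$start), end = as.integer(h$end))
  } else if (!is.null(pdb$helix) && length(pdb$helix$start)) {
    hc <- pdb$helix$chain
    ok <- if (is.null(hc)) rep(TRUE, length(pdb$helix$start))
          else hc %in% chain
    data.frame(start = as.integer(pdb$helix$start[ok]),
               end = as.integer(pdb$helix$end[ok]))
  } else data.frame(start = integer(0), end = integer(0))
  id <- if (is.character(pdbFile))
    sub("\\.[^.]*$", "", basename(pdbFile)) else "protein"
  structureModel(id, coords, ca, helices)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Atomic geometry features of a residue pair
#'
#' For each of the eight neighbour pairs `(i+x, j+y)` of the 3 x 3
#' window around `(i, j)` (excluding the centre), computes five
#' features: mean heavy-atom pair distance, standard deviation of those
#' distances, C-alpha distance, relative residue angle (between the two
#' C-alpha-to-side-chain-centroid vectors, degrees) and inter-helical
#' angle (between the least-squares axes of the helices containing the
#' two residues, degrees, folded to `[0, 90]`).  Unresolvable neighbour
#' residues contribute zeros; a residue outside every helix segment
#' contributes inter-helical angle 0 with a warning.
#'
#' @param s a [StructureModel-class]
#' @param i,j residue indices.
#' @return numeric vector of length 40, neighbour-major.
#' @export
pairAtomicFeatures <- function(s, i, j) {
  nb <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1),
              c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  L <- length(s@coords)
  axes <- helixAxes(s)
  warned <- FALSE
  helixOf <- function(r) {
    h <- which(s@helices$start <= r & s@helices$end >= r)
    if (length(h)) h[1L] else NA_integer_
  }
  five <- function(a, b) {
    if (a < 1L || a > L || b < 1L || b > L) return(numeric(5L))
    A <- s@coords[[a]]
    B <- s@coords[[b]]
    if (is.null(A) || is.null(B) || !nrow(A) || !nrow(B))
      return(numeric(5L))
    D <- crossDistances(A, B)
    devD <- if (length(D) > 1L) sd(D) else 0
    caD <- if (!anyNA(s@ca[a, ]) && !anyNA(s@ca[b, ]))
      sqrt(sum((s@ca[a, ] - s@ca[b, ])^2)) else 0
    ang <- residueAngle(s, a, b)
    ha <- helixOf(a); hb <- helixOf(b)
    if ((is.na(ha) || is.na(hb)) && !warned) {
      warning("residue outside any helix segment; inter-helical angle 0",
              call. = FALSE)
      warned <<- TRUE
    }
    hAng <- if (!is.na(ha) && !is.na(hb) &&
                !is.null(axes[[ha]]) && !is.null(axes[[hb]]))
      vectorAngle(axes[[ha]], axes[[hb]], fold = TRUE) else 0
    c(mean(D), devD, caD, ang, hAng)
  }
  out <- numeric(0)
  for (r in seq_len(nrow(nb)))
    out <- c(out, five(i + nb[r, 1L], j + nb[r, 2L]))
  out
}

crossDistances <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(as.vector(d2), 0))
}

residueAngle <- function(s, a, b) {
  v <- function(r) {
    if (anyNA(s@ca[r, ])) return(NULL)
    m <- s@coords[[r]]
    side <- m[!(rownames(m) %||% rep("", nrow(m))) %in%
                c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
    if (!nrow(side)) return(NULL)
    colMeans(side) - s@ca[r, ]
  }
  va <- v(a)
  vb <- v(b)
  if (is.null(va) || is.null(vb)) return(0)
  vectorAngle(va, vb, fold = FALSE)
}

vectorAngle <- function(u, v, fold = FALSE) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  cosv <- sum(u * v) / (nu * nv)
  if (fold) cosv <- abs(cosv)
  acos(max(-1, min(1, cosv))) * 180 / pi
}

# least-squares axis (first principal direction) of each helix segment
helixAxes <- function(s) {
  lapply(seq_len(nrow(s@helices)), function(h) {
    rng <- s@helices$start[h]:s@helices$end[h]
    pts <- s@ca[rng, , drop = FALSE]
    pts <- pts[!apply(is.na(pts), 1L, any), , drop = FALSE]
    if (nrow(pts) < 2L) return(NULL)
    prcomp(pts)$rotation[, 1L]
  })
}

#' Ground-truth contact labeling from structure
#'
#' A residue pair `(i, j)` with sequence separation `|i - j| >= minSep`
#' is a contact iff the minimum Euclidean distance over all heavy-atom
#' pairs is strictly below `cutoff`; pairs closer in sequence are
#' excluded from both classes (`NA`).  The map is symmetric.
#'
#' @param s a [StructureModel-class]
#' @param minSep minimum sequence separation (default 5).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5.5).
#' @return a [ContactMap-class]
#' @export
labelContacts <- function(s, minSep = 5L, cutoff = 5.5) {
  L <- length(s@coords)
  lab <- matrix(NA_integer_, L, L)
  for (i in seq_len(L)) {
    A <- s@coords[[i]]
    if (is.null(A) || !nrow(A)) next
    jj <- seq_len(L)
    jj <- jj[jj - i >= minSep]
    for (j in jj) {
      B <- s@coords[[j]]
      if (is.null(B) || !nrow(B)) next
      lab[i, j] <- lab[j, i] <-
        if (min(crossDistances(A, B)) < cutoff) 1L else -1L
    }
  }
  new("ContactMap", proteinId = s@proteinId, labels = lab,
      scores = matrix(NA_real_, L, L), minSep = as.integer(minSep),
      cutoff = cutoff)
}

#' Rank principal components by contact predictive power
#'
#' Standardizes the feature rows, fits a full principal-component
#' rotation, scores every component by the discriminative power of its
#' projection against the labels -- `|AUC - 0.5|` by default, or the
#' accuracy margin of a single-feature linear SVM -- and retains the
#' top `nKeep` components by that score instead of by variance.
#'
#' @param X numeric matrix of feature rows.
#' @param y labels (+1/-1).
#' @param nKeep number of components to retain.
#' @param scorer `"auc"` or `"svm"`.
#' @return a [ComponentRanking-class]
#' @export
fitComponentRanking <- function(X, y, nKeep, scorer = c("auc", "svm")) {
  scorer <- match.arg(scorer)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two rows")
  if (!all(c(-1, 1) %in% y)) stop("both classes must be present")
  st <- scaleStats(X)
  Xs <- applyScale(X, st)
  pr <- prcomp(Xs, center = FALSE, scale. = FALSE)
  ncomp <- ncol(pr$rotation)
  if (nKeep > ncomp)
    stop("nKeep exceeds the ", ncomp, " available components")
  scores <- vapply(seq_len(ncomp), function(k) {
    proj <- pr$x[, k]
    if (scorer == "auc") {
      abs(rocScore(proj, y) - 0.5)
    } else {
      m <- solveSoftMargin(matrix(proj), as.integer(y))
      acc <- mean(ifelse(decisionValue(m, matrix(proj)) >= 0, 1, -1) == y)
      max(acc, 1 - acc) - 0.5
    }
  }, 0)
  selected <- order(-scores)[seq_len(nKeep)]
  new("ComponentRanking", center = st$center, scale = st$scale,
      rotation = pr$rotation, scores = scores,
      selected = as.integer(selected), scorer = scorer)
}

#' Project feature rows onto the ranked components
#'
#' @param r a [ComponentRanking-class]
#' @param X numeric matrix conforming to the fitted dimension.
#' @return matrix with `length(r@selected)` columns in rank order.
#' @export
applyComponentRanking <- function(r, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(r@rotation))
    stop("dimension mismatch: expected ", nrow(r@rotation), " columns")
  Xs <- applyScale(X, list(center = r@center, scale = r@scale))
  out <- Xs %*% r@rotation[, r@selected, drop = FALSE]
  colnames(out) <- paste0("PCBest", seq_along(r@selected))
  out
}

#' Assemble the labeled residue-pair feature table of one protein
#'
#' Runs the full feature pipeline: contact labeling from structure,
#' windowed coupling features and atomic geometry features per
#' evaluable pair, and the predictive-power-ranked principal-component
#' reductions (10 sequence + 2 atomic columns by default).
#'
#' @param s a [StructureModel-class]
#' @param cs a [CouplingStack-class]
#' @param minSep,cutoff contact definition, see [labelContacts()].
#' @param nSeqKeep,nAtomicKeep retained component counts.
#' @return a fully labeled [ContactDataset-class] with ids
#'   `"<protein>:<i>-<j>"`.
#' @export
buildPairTable <- function(s, cs, minSep = 5L, cutoff = 5.5,
                           nSeqKeep = 10L, nAtomicKeep = 2L) {
  cm <- labelContacts(s, minSep, cutoff)
  idx <- which(upper.tri(cm@labels) & !is.na(cm@labels), arr.ind = TRUE)
  if (!nrow(idx)) stop("no evaluable residue pairs")
  y <- cm@labels[idx]
  seqRaw <- t(apply(idx, 1L, function(p)
    pairSeqFeatures(cs, p[1L], p[2L])))
  atomRaw <- t(apply(idx, 1L, function(p)
    pairAtomicFeatures(s, p[1L], p[2L])))
  # small proteins yield fewer components than requested: clamp
  maxComp <- min(nrow(seqRaw) - 1L, ncol(seqRaw))
  if (nSeqKeep > maxComp || nAtomicKeep > min(nrow(atomRaw) - 1L,
                                              ncol(atomRaw))) {
    warning("fewer principal components than requested; clamping",
            call. = FALSE)
    nSeqKeep <- min(nSeqKeep, maxComp)
    nAtomicKeep <- min(nAtomicKeep, nrow(atomRaw) - 1L, ncol(atomRaw))
  }
  rs <- fitComponentRanking(seqRaw, y, nSeqKeep)
  ra <- fitComponentRanking(atomRaw, y, nAtomicKeep)
  contactDataset(
    seqFeatures = applyComponentRanking(rs, seqRaw),
    atomicFeatures = applyComponentRanking(ra, atomRaw),
    label = y,
    ids = sprintf("%s:%d-%d", s@proteinId, idx[, 1L], idx[, 2L]))
}
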