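# Shared fixtures and independent brute-force oracles.

# small well-formed dataset: nL labeled (both classes), nU unlabeled
tinyDataset <- function(nL = 8L, nU = 6L, dSeq = 3L, dAtomic = 2L,
                        seed = 42L) {
  set.seed(seed)
  y <- rep(c(1L, -1L), length.out = nL)
  S <- matrix(rnorm((nL + nU) * dSeq), nL + nU) + c(y, rep(0, nU))
  A <- matrix(rnorm((nL + nU) * dAtomic), nL + nU) + 2 * c(y, rep(0, nU))
  if (nU > 0L) A[(nL + 1):(nL + nU), ] <- NA_real_
  contactDataset(S, A, label = c(y, rep(NA_integer_, nU)),
                 hiddenLabel = c(y, rep(c(1L, -1L), length.out = nU)))
}

# a designed instance on which the transductive mechanism is "live":
# two labeled points imply a vertical boundary, but the unlabeled pool
# forms two tight clusters separated by a wide horizontal gap, so label
# switching must correct the initial assignment of half of each cluster
liveInstance <- function(nPerCluster = 20L, seed = 5L) {
  set.seed(seed)
  Slab <- rbind(c(3, 0), c(3.2, 0.3), c(-3, 0), c(-3.2, -0.3))
  ylab <- c(1L, 1L, -1L, -1L)
  Sp <- cbind(rnorm(nPerCluster, 0.3, 0.6), rnorm(nPerCluster, 2.5, 0.25))
  Sn <- cbind(rnorm(nPerCluster, -0.3, 0.6), rnorm(nPerCluster, -2.5, 0.25))
  S <- rbind(Slab, Sp, Sn)
  A <- rbind(matrix(2 * ylab, 4L, 2L),
             matrix(NA_real_, 2L * nPerCluster, 2L))
  yTrue <- c(ylab, rep(1L, nPerCluster), rep(-1L, nPerCluster))
  contactDataset(S, A,
                 label = c(ylab, rep(NA_integer_, 2L * nPerCluster)),
                 hiddenLabel = yTrue)
}

# brute-force confusion tally
oracleConfusion <- function(pred, truth, eligible) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (!eligible[i]) next
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 1 && truth[i] == -1) fp <- fp + 1L
    if (pred[i] == -1 && truth[i] == -1) tn <- tn + 1L
    if (pred[i] == -1 && truth[i] == 1) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Mann-Whitney pair counting with midpoint ties
oracleROC <- function(scores, truth) {
  pos <- which(truth == 1)
  neg <- which(truth == -1)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (scores[i] > scores[j]) 1
                 else if (scores[i] == scores[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive distance-sort neighbour mean
oracleKnn <- function(xSeq, label, d, k) {
  lab <- which(isLabeled(d))
  same <- lab[exampleLabels(d)[lab] == label]
  dist <- vapply(same, function(r)
    sqrt(sum((seqFeatures(d)[r, ] - xSeq)^2)), 0)
  ord <- same[order(dist, exampleIds(d)[same])]
  colMeans(atomicFeatures(d)[ord[seq_len(k)], , drop = FALSE])
}

# independent atom-pair geometry, written as plain loops
oracleAtomicFive <- function(s, a, b) {
  L <- length(s@coords)
  if (a < 1 || a > L || b < 1 || b > L) return(numeric(5))
  A <- s@coords[[a]]; B <- s@coords[[b]]
  if (is.null(A) || is.null(B)) return(numeric(5))
  ds <- c()
  for (p in seq_len(nrow(A))) for (q in seq_len(nrow(B)))
    ds <- c(ds, sqrt(sum((A[p, ] - B[q, ])^2)))
  ang <- function(u, v, fold) {
    if (sqrt(sum(u^2)) == 0 || sqrt(sum(v^2)) == 0) return(0)
    cv <- sum(u * v) / sqrt(sum(u^2)) / sqrt(sum(v^2))
    if (fold) cv <- abs(cv)
    acos(max(-1, min(1, cv))) * 180 / pi
  }
  scv <- function(r) {
    m <- s@coords[[r]]
    keep <- !(rownames(m) %in% c("N", "CA", "C", "O", "OXT"))
    if (!any(keep)) return(NULL)
    colMeans(m[keep, , drop = FALSE]) - s@ca[r, ]
  }
  va <- scv(a); vb <- scv(b)
  resAng <- if (is.null(va) || is.null(vb) || anyNA(s@ca[a, ]) ||
                anyNA(s@ca[b, ])) 0 else ang(va, vb, FALSE)
  hx <- function(r) {
    h <- which(s@helices$start <= r & s@helices$end >= r)[1]
    if (is.na(h)) return(NULL)
    pts <- s@ca[s@helices$start[h]:s@helices$end[h], , drop = FALSE]
    prcomp(pts)$rotation[, 1]
  }
  ha <- hx(a); hb <- hx(b)
  hAng <- if (is.null(ha) || is.null(hb)) 0 else ang(ha, hb, TRUE)
  caD <- if (anyNA(s@ca[a, ]) || anyNA(s@ca[b, ])) 0
         else sqrt(sum((s@ca[a, ] - s@ca[b, ])^2))
  c(mean(ds), if (length(ds) > 1) sd(ds) else 0, caD, resAng, hAng)
}

# random toy structure: nRes residues on two helices, 2-4 atoms each
randomStructure <- function(nRes = 8L, seed = 11L) {
  set.seed(seed)
  coords <- vector("list", nRes)
  ca <- matrix(NA_real_, nRes, 3L)
  for (r in seq_len(nRes)) {
    base <- c(1.6 * r, (r > nRes / 2) * 6, 0)
    nat <- sample(2:4, 1L)
    m <- matrix(rnorm(nat * 3, sd = 0.8), nat) + rep(base, each = nat)
    rownames(m) <- c("CA", "CB", "CG", "CD")[seq_len(nat)]
    coords[[r]] <- m
    ca[r, ] <- m["CA", ]
  }
  structureModel("toy", coords, ca,
                 data.frame(start = c(1L, nRes %/% 2 + 1L),
                            end = c(nRes %/% 2, nRes)))
}

# deterministic coupling stack with distinct method matrices
toyCouplingStack <- function(L = 14L, seed = 3L) {
  set.seed(seed)
  mats <- lapply(1:4, function(m) {
    M <- matrix(rnorm(L * L), L)
    (M + t(M)) / 2 * m
  })
  couplingStack("toy", mats)
}

# history rows where the objective must not increase: consecutive
# solves at identical penalties with a swap and no oracle query
objectiveViolations <- function(h, tol = 1e-6) {
  v <- 0L
  for (i in seq_len(nrow(h))[-1]) {
    if (h$cPlus[i] == h$cPlus[i - 1] && h$cMinus[i] == h$cMinus[i - 1] &&
        h$nSwaps[i] == 1L && h$nQueries[i] == 0L &&
        h$objective[i] > h$objective[i - 1] + tol)
      v <- v + 1L
  }
  v
}
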