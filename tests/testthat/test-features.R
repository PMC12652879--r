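test_that("the offset pattern deduplicates to exactly 25 positions", {
  off <- offsetPositions()
  expect_identical(nrow(off), 25L)
  expect_identical(anyDuplicated(off), 0L)
  # enumeration: 1 origin + 2 per axis offset (6) + 4 per diagonal (3)
  nAxis <- sum(off[, 1L] == 0 | off[, 2L] == 0) - 1L
  expect_identical(nAxis, 12L)
  expect_identical(sum(off[, 1L] != 0 & off[, 2L] != 0), 12L)
})

test_that("windowed coupling features have the documented layout", {
  cs <- toyCouplingStack(L = 14L)
  v <- pairSeqFeatures(cs, 7L, 10L)
  expect_length(v, 300L)
  # first 100 entries are the (i-1, j-1) block
  off <- offsetPositions()
  manual <- numeric(0)
  for (p in seq_len(25L)) for (m in 1:4) {
    px <- 6L + off[p, 1L]; py <- 9L + off[p, 2L]
    manual <- c(manual,
                if (px >= 1 && px <= 14 && py >= 1 && py <= 14)
                  cs@matrices[[m]][px, py] else 0)
  }
  expect_equal(v[1:100], manual)
  # edge pair: the leading block is zero-padded
  vEdge <- pairSeqFeatures(cs, 1L, 5L)
  expect_equal(vEdge[1:100], rep(0, 100L))
  # all-zero matrices give the zero vector; the map is linear
  zero <- couplingStack("z", lapply(1:4, function(i) matrix(0, 6L, 6L)))
  expect_equal(pairSeqFeatures(zero, 2L, 5L), rep(0, 300L))
  cs2 <- couplingStack("d", lapply(cs@matrices, function(m) 2.5 * m))
  expect_equal(pairSeqFeatures(cs2, 7L, 10L), 2.5 * v)
  expect_error(pairSeqFeatures(cs, 0L, 3L), "out of")
})

test_that("atomic pair features: length, toy geometry and oracle", {
  # two single-atom residues 3 A apart, plus resolvable neighbours
  co <- list(
    matrix(c(0, 0, 0), 1L, dimnames = list("CA", NULL)),
    matrix(c(0, 0, 0), 1L, dimnames = list("CA", NULL)),
    matrix(c(3, 0, 0), 1L, dimnames = list("CA", NULL)),
    matrix(c(3, 0, 0), 1L, dimnames = list("CA", NULL)))
  ca <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 0, 0), c(3, 0, 0))
  s <- structureModel("t", co, ca)
  expect_warning(v <- pairAtomicFeatures(s, 1L, 3L), "helix")
  expect_length(v, 40L)
  # neighbour pair (i+1, j+1) = (2, 4): mean 3, deviation 0, Ca dist 3
  expect_equal(v[1:3], c(3, 0, 3))

  # randomly placed toy structure against the independent loop oracle
  st <- randomStructure(nRes = 8L, seed = 31L)
  nb <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1),
              c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  for (pair in list(c(2L, 6L), c(3L, 7L), c(1L, 8L))) {
    got <- pairAtomicFeatures(st, pair[1L], pair[2L])
    want <- numeric(0)
    for (r in seq_len(nrow(nb)))
      want <- c(want, oracleAtomicFive(st, pair[1L] + nb[r, 1L],
                                       pair[2L] + nb[r, 2L]))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("contact labeling applies the strict cutoff and separation", {
  # residues on a line, 1 A apart; residue pairs at |i-j| in {4,5,6}
  mkRes <- function(x) matrix(c(x, 0, 0), 1L,
                              dimnames = list("CA", NULL))
  co <- lapply(c(0, 1, 2, 3, 4, 5.4, 5.5, 10), mkRes)
  ca <- do.call(rbind, lapply(co, as.numeric))
  s <- structureModel("line", co, ca)
  cm <- labelContacts(s, minSep = 5L, cutoff = 5.5)
  expect_identical(cm@labels[1L, 6L], 1L)     # |i-j| = 5, 5.4 A < 5.5
  expect_identical(cm@labels[1L, 7L], -1L)    # exactly 5.5 A: non-contact
  expect_true(is.na(cm@labels[1L, 5L]))       # separation 4: excluded
  expect_identical(cm@labels[1L, 8L], -1L)    # 10 A apart
  expect_identical(cm@labels, t(cm@labels))   # symmetric

  # contact counts are rigid-motion invariant
  st <- randomStructure(nRes = 9L, seed = 17L)
  cm1 <- labelContacts(st)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st2 <- st
  st2@coords <- lapply(st@coords, function(m) {
    out <- m %*% t(R)
    out + rep(c(5, -3, 2), each = nrow(out))
  })
  st2@ca <- st@ca %*% t(R) + rep(c(5, -3, 2), each = nrow(st@ca))
  cm2 <- labelContacts(st2)
  expect_equal(sum(cm1@labels == 1L, na.rm = TRUE),
               sum(cm2@labels == 1L, na.rm = TRUE))
})

test_that("component ranking orders by discriminative power", {
  set.seed(40)
  n <- 120L
  y <- rep(c(1L, -1L), n / 2L)
  # one informative direction buried among noise
  X <- cbind(rnorm(n), y * 2 + rnorm(n, sd = 0.4), rnorm(n))
  r <- fitComponentRanking(X, y, nKeep = 3L)
  # the top component's projection must be (nearly) label-aligned
  proj <- applyComponentRanking(r, X)[, 1L]
  expect_gt(abs(rocScore(proj, y) - 0.5), 0.45)
  # exhaustive per-component AUC matches the stored scores
  Xs <- scale(X)
  rot <- r@rotation
  for (k in seq_len(ncol(rot)))
    expect_equal(r@scores[k],
                 abs(rocScore(drop(Xs %*% rot[, k]), y) - 0.5))
  expect_identical(r@selected, order(-r@scores)[1:3])
  # noise components rank last
  expect_lt(min(r@scores), 0.15)
  expect_error(fitComponentRanking(X, y, nKeep = 9L), "exceeds")
})

test_that("ranking application yields the documented widths and is stable", {
  set.seed(41)
  y <- rep(c(1L, -1L), 30L)
  Xseq <- matrix(rnorm(60 * 300), 60L); Xseq[, 1L] <- Xseq[, 1L] + y
  rs <- fitComponentRanking(Xseq[1:59, ], y[1:59], nKeep = 10L)
  expect_identical(ncol(applyComponentRanking(rs, Xseq)), 10L)
  Xat <- matrix(rnorm(60 * 40), 60L); Xat[, 2L] <- Xat[, 2L] + 2 * y
  ra <- fitComponentRanking(Xat, y, nKeep = 2L)
  expect_identical(ncol(applyComponentRanking(ra, Xat)), 2L)
  # rank ordering is invariant under row permutation
  perm <- sample(60L)
  ra2 <- fitComponentRanking(Xat[perm, ], y[perm], nKeep = 2L)
  expect_identical(ra2@selected, ra@selected)
  expect_error(applyComponentRanking(ra, Xseq), "mismatch")
})

test_that("PDB reading extracts heavy atoms, conformers and helices", {
  pdb <- system.file("extdata", "toy_synthetic.pdb", package = "attsvm")
  s <- readStructureModel(pdb)
  expect_s4_class(s, "StructureModel")
  expect_identical(length(s@coords), 7L)
  # hydrogens dropped
  expect_false(any(grepl("^H", unlist(lapply(s@coords, rownames)))))
  # residue 2 keeps the B conformer of CB (occupancy 0.7 > 0.3)
  expect_equal(unname(s@coords[[2L]]["CB", 1L]), 4.5)
  expect_identical(nrow(s@helices), 2L)
  cm <- labelContacts(s, minSep = 3L, cutoff = 6)
  expect_s4_class(cm, "ContactMap")
})

test_that("the per-protein pair table pipeline assembles end to end", {
  st <- randomStructure(nRes = 12L, seed = 23L)
  cs <- toyCouplingStack(L = 12L)
  d <- buildPairTable(st, cs, minSep = 3L, cutoff = 6,
                      nSeqKeep = 4L, nAtomicKeep = 2L)
  expect_s4_class(d, "ContactDataset")
  expect_identical(unname(featureSchema(d)), c(4L, 2L))
  expect_true(all(isLabeled(d)))
  expect_match(exampleIds(d)[1L], "^toy:[0-9]+-[0-9]+$")
})
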