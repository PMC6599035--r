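test_that("moderated t matches the direct formula and its limits", {
  # equal means -> d = 0
  r0 <- moderatedT(c(1, 2, 3), c(3, 2, 1), s0 = 0.1)
  expect_equal(r0$d, 0)

  # direct-formula oracle
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- moderatedT(x, y, s0 = 0.1)
  expect_equal(r$d, oracleD(x, y, 0.1), tolerance = 1e-12)
  expect_equal(r$d, -3 / (sqrt(2 / 3) + 0.1), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(-3 / sqrt(2 / 3)), df = 4),
               tolerance = 1e-12)

  # s0 -> infinity damps any difference to zero
  expect_lt(abs(moderatedT(x, y, s0 = 1e9)$d), 1e-8)

  # degenerate input
  expect_error(moderatedT(c(1, 1), c(2, 2), s0 = 0), "undefined")
  expect_error(moderatedT(1, c(1, 2)), "two values")
})

test_that("duplicated-column null yields no significant proteins", {
  set.seed(1)
  half <- matrix(rnorm(100 * 3, 25, 0.5), 100, 3)
  m <- cbind(half, half)  # x identical to y, exchangeable null
  colnames(m) <- c("SN1", "SN2", "SN3", "RA1", "RA2", "RA3")
  rownames(m) <- sprintf("p%03d", 1:100)
  vr <- runVolcano(m, volcanoConfig(), seed = 2, group = toyGroups)
  expect_identical(nSignificant(vr), 0L)
})

test_that("permutation engine equals an exhaustive-enumeration oracle", {
  set.seed(7)
  m <- matrix(rnorm(30 * 6, 25, 0.4), 30, 6)
  m[1:3, 1:3] <- m[1:3, 1:3] + 3   # strong signal
  colnames(m) <- names(toyGroups); rownames(m) <- sprintf("p%02d", 1:30)
  cfg <- volcanoConfig(nPermutations = 750)
  vr <- runVolcano(m, cfg, seed = 1, group = toyGroups)
  expect_true(vr@exhaustive)
  expect_identical(vr@nPermutations, 18L)  # 20 distinct minus the 2 trivial

  # independent oracle: enumerate all relabelings with plain loops
  s0 <- cfg$s0
  combs <- combn(6, 3)
  keyO <- paste(1:3, collapse = ",")
  dObs <- apply(m, 1, function(r) oracleD(r[1:3], r[4:6], s0))
  permAbs <- c()
  B <- 0L
  for (ci in seq_len(ncol(combs))) {
    i1 <- combs[, ci]
    key <- paste(sort(i1), collapse = ",")
    mir <- paste(sort(setdiff(1:6, i1)), collapse = ",")
    if (key == keyO || mir == keyO) next
    B <- B + 1L
    permAbs <- c(permAbs,
                 abs(apply(m, 1, function(r)
                   oracleD(r[i1], r[setdiff(1:6, i1)], s0))))
  }
  expect_identical(B, 18L)
  cand <- sort(abs(dObs), decreasing = TRUE)
  fdrOracle <- vapply(seq_along(cand), function(k) {
    min(1, (1 + sum(permAbs >= cand[k] - 1e-12)) / ((B + 1) * k))
  }, numeric(1))
  eligible <- which(fdrOracle <= cfg$fdrQ)
  thrOracle <- if (length(eligible)) cand[max(eligible)] else Inf
  sigOracle <- abs(dObs) >= thrOracle
  tab <- volcanoTable(vr)
  expect_equal(vr@threshold, thrOracle)
  expect_identical(tab$significant, unname(sigOracle))
  expect_equal(tab$d, unname(dObs), tolerance = 1e-12)
})

test_that("sampled permutations are distinct and reproducible", {
  set.seed(3)
  m <- matrix(rnorm(50 * 10, 25, 0.4), 50, 10)
  colnames(m) <- c(paste0("SN", 1:5), paste0("RA", 1:5))
  rownames(m) <- sprintf("p%02d", 1:50)
  g <- rep(c("SN", "RA"), each = 5)
  cfg <- volcanoConfig(nPermutations = 100)
  v1 <- runVolcano(m, cfg, seed = 5, group = g)
  v2 <- runVolcano(m, cfg, seed = 5, group = g)
  expect_false(v1@exhaustive)          # choose(10,5) - 2 = 250 > 100
  expect_identical(v1@nPermutations, 100L)
  expect_identical(volcanoTable(v1)$d, volcanoTable(v2)$d)
  expect_identical(v1@threshold, v2@threshold)
})

test_that("tiny permutation counts are recorded as a warning-level note", {
  m <- completeMatrix(p = 20)
  vr <- runVolcano(m, volcanoConfig(nPermutations = 5), seed = 1,
                   group = toyGroups)
  expect_match(vr@notes, "permutations", all = FALSE)
})

test_that("sanity check flags imputation-driven significance only in scope", {
  set.seed(21)
  p <- 60
  m <- matrix(rnorm(p * 6, 25, 0.3), p, 6,
              dimnames = list(sprintf("p%03d", 1:p), names(toyGroups)))
  colnames(m) <- c("SN1", "SN2", "SN3", "RA1", "RA2", "RA3")
  # p001: genuine strong signal, fully observed -> never flagged
  m[1, 1:3] <- m[1, 1:3] + 4
  # p002: raw evidence says no change, but all RA values missing ->
  # downshift imputation fabricates a fold change -> flag
  m[2, ] <- 26
  m[2, 4:6] <- NA
  pe <- ProteomeExperiment(m, group = toyGroups, scale = "log2")
  pei <- imputeDownshift(pe, seed = 3)
  vr <- runVolcano(pei, volcanoConfig(), seed = 4)
  vr <- imputationSanityCheck(vr, pei)
  tab <- volcanoTable(vr)
  expect_true(tab$significant[1])
  expect_false(tab$flaggedBySanityCheck[1])
  if (tab$significant[2]) expect_true(tab$flaggedBySanityCheck[2])
  # a fully-observed protein is out of scope even when significant
  expect_true(all(!tab$flaggedBySanityCheck[tab$significant &
                                              rowSums(is.na(m)) == 0]))
})

test_that("abundance ranks are dense with averaged ties", {
  r <- ibaqRank(c(1, 10, 100))
  expect_equal(r$rank, c(1, 2, 3))
  expect_equal(r$percentile[3], 1)        # most abundant -> percentile 1
  rt <- ibaqRank(c(5, 5, 1))
  expect_equal(rt$rank, c(2.5, 2.5, 1))
  expect_error(ibaqRank(c(-1, 2)), "non-negative")
})
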