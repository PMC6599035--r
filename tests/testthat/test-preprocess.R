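test_that("isoform collapse keeps the most abundant isoform and drops decoys", {
  m <- matrix(c(2, 3, 5,    # sum 10
                4, 4, 4,    # sum 12 -> retained for group A
                7, 7, 7,    # singleton group B
                9, 9, 9),   # decoy
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A1", "A2", "B", "REV"), paste0("s", 1:3)))
  pe <- ProteomeExperiment(m, group = c("SN", "SN", "RA"), scale = "log2",
                           reverse = c(FALSE, FALSE, FALSE, TRUE),
                           isoformGroup = c("A", "A", "B", "R"))
  out <- collapseIsoforms(pe)
  expect_identical(rownames(out), c("A2", "B"))

  # no shared groups: unchanged apart from flag-row removal
  pe2 <- ProteomeExperiment(m, group = c("SN", "SN", "RA"), scale = "log2",
                            contaminant = c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(rownames(collapseIsoforms(pe2)), c("A1", "A2", "B"))
})

test_that("isoform collapse matches a brute-force group-max oracle", {
  set.seed(5)
  for (rep in 1:5) {
    p <- 40
    m <- matrix(rnorm(p * 6, 20, 3), p, 6,
                dimnames = list(sprintf("r%02d", 1:p), paste0("s", 1:6)))
    m[sample(length(m), 30)] <- NA
    grp <- sample(sprintf("g%02d", 1:15), p, replace = TRUE)
    pe <- ProteomeExperiment(m, group = toyGroups, scale = "log2",
                             isoformGroup = grp)
    got <- rownames(collapseIsoforms(pe))
    tot <- rowSums(m, na.rm = TRUE)
    want <- vapply(split(seq_len(p), grp), function(ix)
      rownames(m)[ix[which.max(tot[ix])]], character(1))
    expect_setequal(got, unname(want))
  }
})

test_that("valid-value filter implements the >=3-in-one-region rule", {
  m <- matrix(NA_real_, 3, 6,
              dimnames = list(c("snOnly", "both2", "rich"),
                              c("SN1", "SN2", "SN3", "RA1", "RA2", "RA3")))
  m["snOnly", 1:3] <- 20       # 3 valid SN, 0 RA -> retained
  m["both2", c(1, 2, 4, 5)] <- 20  # 2 + 2 -> removed
  m["rich", ] <- 20
  pe <- ProteomeExperiment(m, group = toyGroups, scale = "log2")
  out <- filterProteins(pe)
  expect_identical(rownames(out), c("snOnly", "rich"))

  # peptide filter
  pe2 <- ProteomeExperiment(m, group = toyGroups, scale = "log2",
                            peptides = c(3L, 3L, 1L))
  expect_identical(rownames(filterProteins(pe2)), "snOnly")
})

test_that("filter agrees with direct rule evaluation on random patterns", {
  set.seed(9)
  for (rep in 1:10) {
    p <- 100
    m <- matrix(rnorm(p * 6, 20), p, 6,
                dimnames = list(sprintf("p%03d", 1:p), names(toyGroups)))
    m[matrix(runif(p * 6) < 0.45, p, 6)] <- NA
    pep <- sample(1:4, p, replace = TRUE)
    pe <- ProteomeExperiment(m, group = toyGroups, scale = "log2",
                             peptides = pep)
    got <- rownames(filterProteins(pe))
    keep <- vapply(seq_len(p), function(i) {
      (sum(!is.na(m[i, 1:3])) >= 3 || sum(!is.na(m[i, 4:6])) >= 3) &&
        pep[i] >= 2
    }, logical(1))
    expect_identical(got, rownames(m)[keep])
  }
})

test_that("quantile normalisation maps samples onto mean order statistics", {
  # hand-computed: (1,2,3) and (4,5,6) both become (2.5, 3.5, 4.5)
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantileNormalize(m)
  expect_equal(unname(out), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  # identical samples are a fixed point
  m2 <- cbind(x = c(3, 1, 7), y = c(3, 1, 7))
  expect_equal(quantileNormalize(m2), m2)

  # complete samples share identical sorted vectors; medians equal
  set.seed(2)
  m3 <- matrix(rnorm(60, 20, 2), 10, 6)
  out3 <- quantileNormalize(m3)
  sorted <- apply(out3, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  expect_equal(var(apply(out3, 2, median)), 0)

  # all-missing sample is an error naming the sample
  m4 <- cbind(ok = c(1, 2), bad = c(NA_real_, NA_real_))
  expect_error(quantileNormalize(m4), "bad")
})

test_that("quantile normalisation agrees with limma on complete matrices", {
  skip_if_not_installed("limma")
  set.seed(3)
  m <- matrix(rnorm(200 * 6, 25, 2), 200, 6)
  expect_equal(unname(quantileNormalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("downshift imputation has the configured distribution", {
  # one sample with known observed mean/sd and many missing entries
  set.seed(4)
  obs <- rnorm(10000, 20, 1)
  m <- cbind(s1 = c(obs, rep(NA_real_, 10000)),
             s2 = rnorm(20000, 20, 1))
  out <- imputeDownshift(m, width = 0.3, downshift = 1.8, seed = 10)
  mask <- attr(out, "imputedMask")
  imp <- out[mask[, 1], 1]
  mu <- mean(obs); sdv <- sd(obs)
  expect_equal(length(imp), 10000)
  expect_lt(abs(mean(imp) - (mu - 1.8 * sdv)), 4 * 0.3 * sdv / sqrt(10000))
  expect_lt(abs(sd(imp) - 0.3 * sdv), 0.01)
  # distributional shape: Kolmogorov-Smirnov against the target normal
  ks <- suppressWarnings(
    stats::ks.test(imp, "pnorm", mu - 1.8 * sdv, 0.3 * sdv))
  expect_gt(ks$p.value, 0.001)
  # observed entries untouched; counts match
  expect_identical(out[!mask], m[!mask])
  expect_identical(sum(mask), sum(is.na(m)))
})

test_that("imputation leaves complete matrices unchanged and checks inputs", {
  m <- matrix(rnorm(30, 20), 10, 3)
  out <- imputeDownshift(m, seed = 1)
  expect_equal(unclass(out)[, ], m, ignore_attr = TRUE)
  expect_false(any(attr(out, "imputedMask")))
  bad <- cbind(c(1, NA, NA), c(1, 2, 3))
  expect_error(imputeDownshift(bad), "fewer than 2 observed")
})
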