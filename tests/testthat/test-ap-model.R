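test_that("integrator reproduces trivial and closed-form dynamics", {
  # no conductances, no stimulus: V stays at the initial value
  still <- cellModel("still", cm = 50,
                     currents = list(currentSpec("b", g = 0, e = -10)),
                     vInit = -70)
  tr <- runCell(still, duration = 0.2, dt = 1)
  expect_true(all(abs(tr$vm + 70) < 1e-9))

  # single ohmic leak: exponential relaxation V(t) = E + (V0-E) e^{-t g/C}
  leak <- cellModel("leak", cm = 20,
                    currents = list(currentSpec("L", g = 2, e = -60)),
                    vInit = -20)
  tr2 <- runCell(leak, duration = 0.3, dt = 0.5, rtol = 1e-9, atol = 1e-9)
  expected <- -60 + (-20 + 60) * exp(-tr2$time * 2 / 20)
  expect_equal(tr2$vm, expected, tolerance = 1e-6)
})

test_that("paced atrial model fires one AP per stimulus, unpaced it rests", {
  am <- atrialCellModel()
  tr <- runCell(am, duration = 2, dt = 0.5)
  expect_lt(diff(range(tr$vm)), 3)  # quiescent drift only
  da <- detectAutomaticity(tr)
  expect_false(da$spontaneous)

  trp <- runCell(am, duration = 2, dt = 0.5,
                 pacing = list(cycleLength = 200))
  up <- pacemakeR:::findUpstrokes(trp$time, trp$vm)
  expect_identical(length(up), 10L)  # duration/cycleLength upstrokes
})

test_that("conversion applies the documented field edits", {
  am <- atrialCellModel()
  sn <- convertAtrialToSN(am)
  expect_equal(capacitance(sn), 25)
  expect_equal(conductance(sn, "Kur"), 0)
  expect_equal(conductance(sn, "to"), 0.1 * conductance(am, "to"))
  expect_equal(conductance(sn, "Na"), 0.4 * conductance(am, "Na"))
  expect_equal(conductance(sn, "K1"), conductance(am, "K1"))  # unchanged
  expect_true(all(c("f", "CaT") %in% names(sn@currents)))
  # T-type half-activation shifted by -7 mV relative to the inserted spec
  st <- defaultScalingTable()
  expect_equal(sn@currents$CaT$gates[[1]]$vHalf,
               st$insert$CaT$gates[[1]]$vHalf - 7)
  # scaling an absent current is an error
  bad <- st; bad$ratios <- c(bad$ratios, Ks = 2)
  expect_error(convertAtrialToSN(am, bad), "Ks")
})

test_that("identity scaling is a no-op and the round trip is exact", {
  am <- atrialCellModel()
  ident <- defaultScalingTable()
  ident$ratios[] <- 1; ident$fractions[] <- 1; ident$calcium[] <- 1
  ident$insert <- list(); ident$insertRatio <- numeric()
  ident$shifts <- list(); ident$snCm <- am@cm
  same <- convertAtrialToSN(am, ident)
  expect_identical(same@currents, am@currents)
  expect_identical(same@cm, am@cm)
  expect_identical(same@vInit, am@vInit)

  rt <- convertSNToAtrial(convertAtrialToSN(am))
  expect_identical(rt@currents, am@currents)
  expect_identical(rt@cm, am@cm)
  expect_identical(rt@calcium, am@calcium)
  expect_identical(rt@vInit, am@vInit)
})

test_that("LFQ scaling ratios are 2^log2fc with geometric pooling", {
  res <- S4Vectors::DataFrame(
    protein = c("Scn5a", "Cacna1c", "Kcnh2", "Kcnh2b"),
    log2fc = c(0, 1, 2, 4),
    d = 0, p = 1, significant = FALSE, direction = "none")
  vr <- new("VolcanoResults", results = res, config = list(fdrQ = 0.05),
            threshold = Inf, nPermutations = 18L, exhaustive = TRUE,
            fdrAtThreshold = NA_real_, seed = 1L, notes = character())
  mapping <- data.frame(protein = c("Scn5a", "Cacna1c", "Kcnh2", "Kcnh2b"),
                        current = c("Na", "CaL", "Kr", "Kr"))
  r <- computeScalingFromLFQ(vr, mapping)
  expect_equal(r[["Na"]], 1, tolerance = 1e-12)
  expect_equal(r[["CaL"]], 2, tolerance = 1e-12)
  expect_equal(r[["Kr"]], 2^3, tolerance = 1e-12)  # geometric mean of 2,4
  expect_warning(
    computeScalingFromLFQ(vr, data.frame(protein = "Hcn9",
                                         current = "fX")), "fX")
})

test_that("automaticity detector classifies constructed waveforms", {
  # flat trace
  flat <- data.frame(time = seq(0, 4000, by = 1), vm = -78, stim = 0)
  expect_false(detectAutomaticity(flat)$spontaneous)
  # periodic 5 Hz train
  tr <- triangularAPTrain(nAP = 22, clMs = 200)
  da <- detectAutomaticity(tr)
  expect_true(da$spontaneous)
  expect_equal(da$rate, 5, tolerance = 0.02)
  # a single upstroke in the window is inconclusive
  one <- triangularAPTrain(nAP = 1, clMs = 800)
  expect_true(is.na(detectAutomaticity(one, windowFraction = 1)$spontaneous))
  # paced trace with stimulus channel masked counts no spontaneous upstrokes
  am <- atrialCellModel()
  trp <- runCell(am, duration = 2, dt = 0.5,
                 pacing = list(cycleLength = 200))
  expect_false(detectAutomaticity(trp)$spontaneous)
})

test_that("feature extraction matches triangular-waveform geometry", {
  tr <- triangularAPTrain(nAP = 4, clMs = 200, peak = 20, mdp = -60,
                          riseMs = 2, fallMs = 100)
  f <- extractFeatures(tr)
  expect_equal(f$mdp, -60, tolerance = 1e-6)
  expect_equal(f$overshoot, 20, tolerance = 1e-6)
  expect_equal(f$cycleLength, 200, tolerance = 0.01)
  # linear repolarisation: APDx = x * fallMs (takeoff at upstroke start)
  expect_equal(f$apd50, 0.5 * 100 + 2, tolerance = 0.5)
  expect_equal(f$apd90, 0.9 * 100 + 2, tolerance = 0.5)
  expect_lte(f$apd50, f$apd90)
  # two identical APs -> zero variance between per-AP features (mean is
  # exactly the per-AP value)
  expect_equal(f$dvdtMax, (20 + 60) / 2 / 1000 * 1000, tolerance = 0.05)
  # clipped trace: MDP equals the clip level
  tr2 <- tr; tr2$vm <- pmax(tr2$vm, -55)
  expect_equal(extractFeatures(tr2)$mdp, -55, tolerance = 1e-6)
  expect_error(extractFeatures(triangularAPTrain(nAP = 1)), "fewer than 2")
})

test_that("steady-state charge balance holds over a spontaneous cycle", {
  sn <- sinusNodeCellModel()
  tr <- runCell(sn, duration = 10, dt = 0.25)
  up <- pacemakeR:::findUpstrokes(tr$time, tr$vm)
  i1 <- up[length(up) - 1L]; i2 <- up[length(up)]
  seg <- tr[i1:i2, ]
  iTot <- rowSums(seg[, grep("^I\\.", names(seg)), drop = FALSE])
  # mean total membrane current over one steady-state cycle ~ 0
  expect_lt(abs(mean(iTot)) / capacitance(sn), 1e-2)  # pA/pF
})

test_that("halving the output step leaves the trace unchanged", {
  sn <- sinusNodeCellModel()
  t1 <- runCell(sn, duration = 1.5, dt = 0.2, rtol = 1e-8, atol = 1e-8)
  t2 <- runCell(sn, duration = 1.5, dt = 0.1, rtol = 1e-8, atol = 1e-8)
  common <- match(round(t1$time, 6), round(t2$time, 6))
  expect_lt(max(abs(t1$vm - t2$vm[common])), 0.5)
})

test_that("divergent dynamics raise an informative error", {
  runaway <- cellModel("bad", cm = 1,
                       currents = list(currentSpec("inw", g = 50, e = 300)),
                       vInit = -70)
  expect_error(runCell(runaway, duration = 0.5, dt = 1), "diverged")
})
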