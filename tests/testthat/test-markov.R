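test_that("HH-to-Markov rate mapping preserves steady state and tau", {
  r <- hhToMarkov(function(V) 0.5 + 0 * V, function(V) 10 + 0 * V)
  expect_equal(r$alpha(-80), 0.05)
  expect_equal(r$beta(-80), 0.05)
  # yInf = 1 -> beta = 0
  r1 <- hhToMarkov(function(V) 1 + 0 * V, function(V) 5 + 0 * V)
  expect_equal(r1$beta(0), 0)
  # algebraic identity over 100 voltages
  yi <- function(V) 1 / (1 + exp((V + 87) / 9.6))
  tau <- function(V) 130 + 600 * exp(-((V + 87) / 25)^2)
  rr <- hhToMarkov(yi, tau)
  V <- seq(-140, 20, length.out = 100)
  a <- rr$alpha(V); b <- rr$beta(V)
  expect_equal(a / (a + b), yi(V), tolerance = 1e-12)
  expect_equal(1 / (a + b), tau(V), tolerance = 1e-12)
  # non-positive tau is rejected
  bad <- hhToMarkov(function(V) 0.5, function(V) -1)
  expect_error(bad$alpha(0), "positive")
})

test_that("no current flows at the reversal potential", {
  sc <- hcn4Scheme(eRev = -30)
  ss <- simulateUnitarySweeps(sc, voltageProtocol(-30, -30, 500), 5,
                              seed = 1)
  expect_true(all(ss@sweeps == 0))
})

test_that("open fraction and dwell times match the chain's law", {
  # fast two-state gate so that tens of thousands of sojourns accumulate
  sc <- twoStateScheme("fast2", function(V) 0.4 + 0 * V,
                       function(V) 4 + 0 * V, gU = 1, eRev = 0)
  V <- -80
  a <- sc@rates[["C->O"]](V); b <- sc@rates[["O->C"]](V)
  ss <- simulateUnitarySweeps(sc, voltageProtocol(V, V, 60000,
                                                  sampleDt = 0.02),
                              nSweeps = 2, seed = 2)
  fOpen <- mean(ss@sweeps != 0)
  pInf <- a / (a + b)
  nEff <- 2 * 60000 / (1 / (a + b))  # effective independent draws
  se <- sqrt(pInf * (1 - pInf) / nEff)
  expect_lt(abs(fOpen - pInf), 6 * se)

  # open dwell times: geometric in steps, exponential with mean 1/beta in
  # the small-step limit (Kolmogorov-Smirnov at n = 5000)
  dw <- unlist(lapply(seq_len(nrow(ss@sweeps)), function(i) {
    r <- rle(ss@sweeps[i, ] != 0)
    r$lengths[r$values][-1]
  }))
  dw <- dw * 0.02
  expect_gt(length(dw), 5000)
  ks <- suppressWarnings(stats::ks.test(dw[seq_len(5000)], "pexp", b))
  expect_gt(ks$p.value, 1e-4)
  expect_lt(abs(mean(dw) - 1 / b) / (1 / b), 0.05)
})

test_that("geometric-sojourn engine matches a literal per-step chain", {
  # same discrete-time law: compare open fractions and transition counts
  sc <- hcn4Scheme()
  V <- -95
  dt <- 0.02
  a <- sc@rates[["C->O"]](V) * dt; b <- sc@rates[["O->C"]](V) * dt
  set.seed(11)
  oracleStates <- oracleBernoulliChain(a, b, 4e5, state0 = 1L)
  ss <- simulateUnitarySweeps(sc, voltageProtocol(V, V, 4e5 * dt,
                                                  sampleDt = dt),
                              nSweeps = 1, seed = 12)
  fo1 <- mean(oracleStates == 2L)
  fo2 <- mean(ss@sweeps[1, ] != 0)
  pInf <- a / (a + b)
  se <- sqrt(pInf * (1 - pInf) / (4e5 * dt / (1 / (a / dt + b / dt))))
  expect_lt(abs(fo1 - fo2), 6 * se)
})

test_that("ensemble averages are pointwise means and linear", {
  sc <- hcn4Scheme()
  ss <- simulateUnitarySweeps(sc, hcn4ActivationProtocol(duration = 200),
                              nSweeps = 6, seed = 3)
  ea <- ensembleAverage(ss)
  expect_equal(ea$current, colMeans(ss@sweeps))
  # single sweep averages to itself
  s1 <- new("SweepSet", sweeps = ss@sweeps[1, , drop = FALSE],
            time = ss@time, voltage = ss@voltage, scheme = sc,
            dtMc = ss@dtMc, seed = 1L)
  expect_equal(ensembleAverage(s1)$current, ss@sweeps[1, ])
  # linearity of pooled means
  a <- ss@sweeps[1:2, , drop = FALSE]; b <- ss@sweeps[3:6, , drop = FALSE]
  expect_equal(colMeans(ss@sweeps) * 6,
               colMeans(a) * 2 + colMeans(b) * 4)
})

test_that("master equation conserves probability and matches closed form", {
  sc <- hcn4Scheme()
  od <- occupancyODE(sc, hcn4ActivationProtocol())
  expect_true(all(abs(od$C + od$O - 1) <= 1e-8))
  # two-state fixed V: p(t) = pInf + (p0 - pInf) exp(-t/tau)
  V <- -90
  a <- sc@rates[["C->O"]](V); b <- sc@rates[["O->C"]](V)
  p0 <- pacemakeR:::stationaryDist(sc, -30)["O"]
  expect_equal(od$pOpen,
               analyticTwoState(a, b, unname(p0), od$time),
               tolerance = 1e-6)
})

test_that("Monte-Carlo ensembles converge to the master equation as 1/sqrt(n)", {
  sc <- hcn4Scheme()
  prot <- hcn4ActivationProtocol(duration = 1000, sampleDt = 10)
  od <- occupancyODE(sc, prot, dt = 10)
  tPts <- seq(100, 1000, by = 100)
  iOd <- match(tPts, round(od$time))
  odAt <- od$current[iOd]
  for (n in c(100, 1000, 10000)) {
    ss <- simulateUnitarySweeps(sc, prot, nSweeps = n, seed = 100 + n)
    ea <- ensembleAverage(ss)
    eaAt <- ea$current[match(tPts, round(ea$time))]
    # binomial MC standard error of the mean current at each time point
    p <- pmin(pmax(od$pOpen[iOd], 1e-6), 1 - 1e-6)
    u <- sc@gU * (-90 - sc@eRev) / 1000
    se <- abs(u) * sqrt(p * (1 - p) / n)
    expect_true(all(abs(eaAt - odAt) <= 5 * se + 1e-4 / sqrt(n)))
  }
})

test_that("unitary conductance is recovered from noiseless open levels", {
  sc <- hcn4Scheme(gU = 1.0, eRev = -30)
  sets <- lapply(c(-90, -70, -50), function(v) {
    sw <- matrix(c(0, sc@gU * (v - sc@eRev) / 1000), 1, 2)
    new("SweepSet", sweeps = sw, time = c(1, 2),
        voltage = rep(v, 2), scheme = sc, dtMc = 0.02, seed = 1L)
  })
  fit <- fitUnitaryConductance(sets)
  expect_equal(fit$gFit, 1.0, tolerance = 1e-12)
  expect_equal(fit$eRevFit, -30, tolerance = 1e-9)
  # doubling gU doubles the fitted slope
  sc2 <- hcn4Scheme(gU = 2.0)
  sets2 <- lapply(sets, function(s) {
    s@sweeps <- s@sweeps * 2; s@scheme <- sc2; s
  })
  expect_equal(fitUnitaryConductance(sets2)$gFit, 2.0, tolerance = 1e-12)
  # all-closed sweeps cannot be fitted
  closed <- lapply(sets, function(s) { s@sweeps[] <- 0; s })
  expect_error(fitUnitaryConductance(closed), "opening")
})

test_that("channel counting rounds the conductance ratio", {
  expect_identical(channelCountFromConductance(0.001, 1), 1L)
  expect_identical(channelCountFromConductance(6.255, 1.0), 6255L)
  # reconstruction: N channels at open probability p give back the cell
  # conductance within rounding
  sc <- hcn4Scheme()
  N <- channelCountFromConductance(4.2, sc@gU)
  od <- occupancyODE(sc, hcn4ActivationProtocol(duration = 100),
                     nChannels = N)
  g <- od$current / (od$voltage - sc@eRev) / od$pOpen  # nS, where defined
  ok <- is.finite(g) & od$pOpen > 1e-6
  expect_true(all(abs(g[ok] - 4.2) < sc@gU / 1000))
})

test_that("too-coarse Monte Carlo steps are rejected", {
  fast <- twoStateScheme("fast", function(V) 0.5 + 0 * V,
                         function(V) 0.05 + 0 * V, gU = 1, eRev = 0)
  expect_error(
    simulateUnitarySweeps(fast, voltageProtocol(-80, -80, 10,
                                                sampleDt = 0.02),
                          1, seed = 1, dtMc = 0.02),
    "smaller dtMc")
})
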