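#' Convert Hodgkin-Huxley gating to two-state Markov rates
#'
#' For an HH gate with steady state y_inf(V) and time constant tau(V) (ms),
#' the unique two-state C<->O scheme whose open-state occupancy reproduces
#' the gate has opening rate alpha(V) = y_inf(V)/tau(V) and closing rate
#' beta(V) = (1 - y_inf(V))/tau(V); then alpha/(alpha+beta) = y_inf and
#' 1/(alpha+beta) = tau identically.
#'
#' @param yInf function of voltage (mV) returning values in [0, 1].
#' @param tau function of voltage (mV) returning a positive time constant
#'   in ms.
#' @return list with rate functions \code{alpha} and \code{beta} (1/ms).
#' @examples
#' r <- hhToMarkov(function(V) 0.5, function(V) 10)
#' r$alpha(-80) # 0.05 /ms
#' @export
hhToMarkov <- function(yInf, tau) {
  force(yInf); force(tau)
  check <- function(V) {
    tv <- tau(V)
    if (any(!is.finite(tv)) || any(tv <= 0))
      stop("tau(V) must be positive on the protocol voltage range")
    yv <- yInf(V)
    if (any(yv < 0) || any(yv > 1))
      stop("yInf(V) must lie in [0, 1]")
    list(y = yv, tau = tv)
  }
  list(
    alpha = function(V) { g <- check(V); g$y / g$tau },
    beta = function(V) { g <- check(V); (1 - g$y) / g$tau }
  )
}

#' Two-state single-channel scheme from an HH gate
#'
#' @param name channel name.
#' @param yInf,tau HH activation gate functions of voltage (see
#'   [hhToMarkov()]).
#' @param gU unitary conductance (pS).
#' @param eRev reversal potential (mV).
#' @return a [MarkovScheme-class] with states C and O.
#' @export
twoStateScheme <- function(name, yInf, tau, gU, eRev) {
  r <- hhToMarkov(yInf, tau)
  new("MarkovScheme", name = name, states = c("C", "O"),
      rates = list("C->O" = r$alpha, "O->C" = r$beta),
      conducting = "O", gU = gU, eRev = eRev)
}

#' Four-state single-channel scheme with two inactive states
#'
#' Linear chain C <-> O <-> I1 <-> I2 for channels with inactivation
#' (L-/T-type Ca2+ channels, ERG). Activation drives the C <-> O edge via
#' [hhToMarkov()]; inactivation drives O <-> I1, and I1 <-> I2 is a slower
#' replica (factor \code{slowFactor}) of the same inactivation rates,
#' giving a deep inactivated state. The chain topology within "two
#' additional inactive states" is a modelling choice documented in the
#' methods vignette.
#'
#' @param name channel name.
#' @param actInf,actTau activation gate functions of voltage.
#' @param inactInf,inactTau inactivation gate functions (inactInf is the
#'   availability, 1 = fully available).
#' @param gU unitary conductance (pS).
#' @param eRev reversal potential (mV).
#' @param slowFactor rate multiplier for the I1 <-> I2 edge (default 0.1).
#' @return a [MarkovScheme-class] with states C, O, I1, I2.
#' @export
fourStateScheme <- function(name, actInf, actTau, inactInf, inactTau,
                            gU, eRev, slowFactor = 0.1) {
  a <- hhToMarkov(actInf, actTau)
  h <- hhToMarkov(inactInf, inactTau)
  new("MarkovScheme", name = name, states = c("C", "O", "I1", "I2"),
      rates = list(
        "C->O" = a$alpha, "O->C" = a$beta,
        "O->I1" = h$beta, "I1->O" = h$alpha,
        "I1->I2" = function(V) slowFactor * h$beta(V),
        "I2->I1" = function(V) slowFactor * h$alpha(V)
      ),
      conducting = "O", gU = gU, eRev = eRev)
}

#' Shipped HCN4 pacemaker-channel scheme
#'
#' Two-state C<->O scheme for the HCN4 funny channel: Boltzmann activation
#' with half-activation -87 mV and slope 9.6 mV (activated by
#' hyperpolarisation), bell-shaped time constant peaking near the
#' half-activation voltage, unitary conductance 1.0 pS and reversal
#' potential -30 mV. Kinetic parameters are this package's
#' parameterisation of standard sinoatrial funny-current gating.
#'
#' @param gU unitary conductance in pS (default 1.0).
#' @param eRev reversal potential in mV (default -30).
#' @return a [MarkovScheme-class].
#' @export
hcn4Scheme <- function(gU = 1.0, eRev = -30) {
  twoStateScheme(
    "Hcn4",
    yInf = function(V) 1 / (1 + exp((V + 87) / 9.6)),
    tau = function(V) 130 + 600 * exp(-((V + 87) / 25)^2),
    gU = gU, eRev = eRev
  )
}

#' Shipped Cav1.2 scheme (placeholder conductance)
#'
#' Four-state C-O-I1-I2 scheme for the L-type Ca2+ channel. The unitary
#' conductance default is a placeholder typical of L-type channels in
#' physiological Ca2+ and should be overridden from the user's
#' configuration when absolute numbers matter.
#'
#' @param gU unitary conductance in pS (placeholder default 2.0).
#' @param eRev reversal potential in mV (default +50).
#' @return a [MarkovScheme-class].
#' @export
cav12Scheme <- function(gU = 2.0, eRev = 50) {
  fourStateScheme(
    "Cav1.2",
    actInf = function(V) 1 / (1 + exp(-(V + 10) / 6)),
    actTau = function(V) 1 + 2 * exp(-((V + 15) / 20)^2),
    inactInf = function(V) 1 / (1 + exp((V + 35) / 6)),
    inactTau = function(V) 20 + 30 * exp(-((V + 20) / 25)^2),
    gU = gU, eRev = eRev
  )
}

#' Construct a voltage-clamp protocol
#'
#' @param holdingV holding potential (mV).
#' @param v test potentials (mV), one per step.
#' @param duration step durations (ms), recycled against \code{v}.
#' @param sampleDt sampling interval (ms, default 1); must be an integer
#'   multiple of the Monte Carlo step when simulated.
#' @return a [VoltageProtocol-class].
#' @export
voltageProtocol <- function(holdingV, v, duration, sampleDt = 1) {
  new("VoltageProtocol", holdingV = holdingV,
      steps = data.frame(v = v,
                         duration = rep_len(duration, length(v))),
      sampleDt = sampleDt)
}

#' The single-channel activation protocol of the shipped HCN4 analysis
#'
#' A hyperpolarising pulse from a holding potential of -30 mV to -90 mV
#' for 2000 ms, the protocol used to display unitary sweeps and their
#' ensemble average.
#'
#' @param vTest test potential (default -90 mV).
#' @param duration pulse duration (default 2000 ms).
#' @param sampleDt sampling interval (default 1 ms).
#' @return a [VoltageProtocol-class].
#' @export
hcn4ActivationProtocol <- function(vTest = -90, duration = 2000,
                                   sampleDt = 1) {
  voltageProtocol(holdingV = -30, v = vTest, duration = duration,
                  sampleDt = sampleDt)
}

# transition-rate matrix Q at voltage V: Q[i, j] = rate i -> j, diagonal
# set so rows sum to zero
rateMatrix <- function(scheme, V) {
  k <- length(scheme@states)
  Q <- matrix(0, k, k, dimnames = list(scheme@states, scheme@states))
  for (e in names(scheme@rates)) {
    ft <- strsplit(e, "->", fixed = TRUE)[[1]]
    r <- scheme@rates[[e]](V)
    if (r < 0) stop("negative rate on edge ", e, " at V = ", V)
    Q[ft[1L], ft[2L]] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of the chain at fixed voltage
stationaryDist <- function(scheme, V) {
  Q <- rateMatrix(scheme, V)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- qr.solve(A, b)
  p <- pmax(p, 0)
  p / sum(p)
}

#' Monte Carlo simulation of unitary single-channel sweeps
#'
#' Simulates the discrete-time jump process that mimics single-channel
#' gating: at each Monte Carlo step of length \code{dtMc} (default 0.02 ms)
#' the channel moves from state i to state j with probability
#' r_ij(V) * dtMc. Sojourn lengths of this chain are geometric, and the
#' simulation draws them directly (an exact, loop-free realisation of the
#' same process). Each sweep starts from the stationary state distribution
#' at the holding potential; the recorded unitary current is
#' gU * (V - eRev) / 1000 pA while the conducting state is occupied and 0
#' otherwise. The step size must satisfy (max total exit rate) * dtMc <
#' 0.1, which keeps the discrete chain close to the continuous-time
#' process; larger products raise an error demanding a smaller step.
#'
#' @param scheme a [MarkovScheme-class].
#' @param protocol a [VoltageProtocol-class].
#' @param nSweeps number of consecutive sweeps.
#' @param seed integer seed (Mersenne-Twister).
#' @param dtMc Monte Carlo step in ms (default 0.02).
#' @return a [SweepSet-class].
#' @export
simulateUnitarySweeps <- function(scheme, protocol, nSweeps = 100L,
                                  seed = 1L, dtMc = 0.02) {
  validObject(scheme); validObject(protocol)
  steps <- protocol@steps
  sampleEvery <- protocol@sampleDt / dtMc
  if (abs(sampleEvery - round(sampleEvery)) > 1e-9)
    stop("sampleDt must be an integer multiple of dtMc")
  sampleEvery <- as.integer(round(sampleEvery))

  segQ <- lapply(steps$v, function(v) rateMatrix(scheme, v))
  exitP <- lapply(segQ, function(Q) -diag(Q) * dtMc)
  maxExit <- max(vapply(exitP, max, numeric(1)))
  if (maxExit >= 0.1)
    stop(sprintf(
      "transition probability per step reaches %.3g (>= 0.1); use a smaller dtMc",
      maxExit))
  segSteps <- as.integer(round(steps$duration / dtMc))
  nTotal <- sum(segSteps)
  nSamples <- nTotal %/% sampleEvery
  sampleV <- rep(steps$v, times = segSteps)[seq_len(nSamples) * sampleEvery]
  time <- seq_len(nSamples) * protocol@sampleDt

  stateNames <- scheme@states
  openIdx <- match(scheme@conducting, stateNames)
  p0 <- stationaryDist(scheme, protocol@holdingV)
  # per-segment destination tables
  dest <- lapply(segQ, function(Q) {
    lapply(seq_len(nrow(Q)), function(i) {
      r <- Q[i, ]; r[i] <- 0
      j <- which(r > 0)
      list(j = j, p = r[j] / sum(r[j]))
    })
  })

  sweeps <- matrix(0, nSweeps, nSamples)
  segEnd <- cumsum(segSteps)
  segStart <- c(0L, head(segEnd, -1L))
  withSeed(seed, {
    for (sw in seq_len(nSweeps)) {
      st <- sample.int(length(stateNames), 1L, prob = p0)
      openRuns <- NULL  # sample indices where open, collected per sojourn
      for (sg in seq_along(segSteps)) {
        pos <- segStart[sg]          # global steps consumed so far
        last <- segEnd[sg]
        pe <- exitP[[sg]]
        while (pos < last) {
          pExit <- pe[st]
          if (pExit <= 0) {
            dwell <- last - pos
            jumped <- FALSE
          } else {
            k <- rgeom(1L, pExit) + 1L
            jumped <- k <= last - pos
            dwell <- min(k, last - pos)
          }
          if (st == openIdx) {
            s1 <- (pos %/% sampleEvery) + 1L
            s2 <- (pos + dwell) %/% sampleEvery
            if (s2 >= s1) openRuns <- c(openRuns, s1:s2)
          }
          pos <- pos + dwell
          if (jumped) {
            d <- dest[[sg]][[st]]
            st <- if (length(d$j) == 1L) d$j
                  else d$j[sample.int(length(d$j), 1L, prob = d$p)]
          }
        }
      }
      if (length(openRuns))
        sweeps[sw, openRuns] <- scheme@gU * (sampleV[openRuns] - scheme@eRev) / 1000
    }
  })
  new("SweepSet", sweeps = sweeps, time = time, voltage = sampleV,
      scheme = scheme, dtMc = dtMc, seed = as.integer(seed))
}

setMethod("show", "SweepSet", function(object) {
  cat("SweepSet:", nrow(object@sweeps), "sweeps x",
      ncol(object@sweeps), "samples (", object@scheme@name, ")\n")
  cat(sprintf("  dtMc %.3g ms, sampled every %.3g ms, open fraction %.3g\n",
              object@dtMc, diff(object@time[1:2]),
              mean(object@sweeps != 0)))
  invisible(object)
})

#' Ensemble-average current of a sweep set
#'
#' @param sweepSet a [SweepSet-class].
#' @return data.frame with \code{time} (ms) and \code{current} (pA), the
#'   pointwise mean across sweeps.
#' @export
ensembleAverage <- function(sweepSet) {
  data.frame(time = sweepSet@time,
             current = colMeans(sweepSet@sweeps))
}

#' Fit the unitary conductance from sweeps at multiple test voltages
#'
#' For each test potential, takes the maximum-magnitude open-level current
#' observed across the sweeps, then fits a least-squares line of current
#' against voltage; the slope is the unitary conductance. Voltages at
#' which the channel never opened cannot contribute a point.
#'
#' @param sweepSets list of [SweepSet-class] objects, one per test
#'   potential (single-step protocols).
#' @return list with \code{gFit} (pS), \code{eRevFit} (mV, the fitted
#'   zero-current voltage) and the per-voltage points used.
#' @export
fitUnitaryConductance <- function(sweepSets) {
  pts <- lapply(sweepSets, function(ss) {
    v <- unique(ss@voltage)
    if (length(v) != 1L)
      stop("each sweep set must hold a single test potential")
    op <- ss@sweeps[ss@sweeps != 0]
    if (!length(op)) return(NULL)
    data.frame(v = v, i = op[which.max(abs(op))])
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0L)
    stop("no channel opening at any voltage; simulate longer or more sweeps")
  if (nrow(pts) < 3L)
    stop("open events at fewer than 3 voltages; simulate longer or more sweeps")
  fit <- lm(i ~ v, data = pts)
  slope <- unname(coef(fit)[2L])
  list(gFit = slope * 1000, eRevFit = -unname(coef(fit)[1L]) / slope,
       points = pts)
}

#' Deterministic state-occupancy solution of a Markov scheme
#'
#' Integrates the master equation dp/dt = Q(V)' p across the protocol with
#' a stiff-capable solver, starting from the stationary distribution at
#' the holding potential, and returns the expected whole-cell current for
#' \code{nChannels} identical channels:
#' I(t) = N * pOpen(t) * gU * (V - eRev) / 1000 (pA).
#'
#' @param scheme a [MarkovScheme-class].
#' @param protocol a [VoltageProtocol-class].
#' @param nChannels number of channels (default 1).
#' @param dt output time step in ms (default \code{protocol@sampleDt}).
#' @param rtol,atol solver tolerances.
#' @return data.frame: \code{time}, one probability column per state,
#'   \code{pOpen}, \code{voltage}, \code{current} (pA).
#' @export
occupancyODE <- function(scheme, protocol, nChannels = 1, dt = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  validObject(scheme); validObject(protocol)
  dt <- dt %||% protocol@sampleDt
  p <- stationaryDist(scheme, protocol@holdingV)
  out <- NULL
  t0 <- 0
  for (sg in seq_len(nrow(protocol@steps))) {
    v <- protocol@steps$v[sg]
    dur <- protocol@steps$duration[sg]
    Qt <- t(rateMatrix(scheme, v))
    times <- seq(0, dur, by = dt)
    sol <- deSolve::lsoda(
      y = p, times = times,
      func = function(t, y, parms) list(parms %*% y),
      parms = Qt, rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1L] < 0)
      stop("master-equation solver failed in segment ", sg,
           " (V = ", v, " mV)")
    seg <- as.data.frame(sol)
    colnames(seg) <- c("time", scheme@states)
    seg$time <- seg$time + t0
    seg$voltage <- v
    keep <- if (sg == 1L) TRUE else seg$time > t0
    out <- rbind(out, seg[keep, ])
    p <- as.numeric(sol[nrow(sol), -1L])
    t0 <- t0 + dur
  }
  out$pOpen <- out[[scheme@conducting]]
  out$current <- nChannels * out$pOpen * scheme@gU *
    (out$voltage - scheme@eRev) / 1000
  rownames(out) <- NULL
  out
}

#' Channel count from whole-cell and unitary conductance
#'
#' The number of channels needed to account for a whole-cell conductance:
#' N = round(G_cell / g_u).
#'
#' @param gCell whole-cell conductance in nS.
#' @param gU unitary conductance in pS.
#' @return integer channel count.
#' @examples
#' channelCountFromConductance(6.255, 1.0) # 6255
#' @export
channelCountFromConductance <- function(gCell, gU) {
  stopifnot(gCell > 0, gU > 0)
  as.integer(round(gCell * 1000 / gU))
}
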