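#' Parametric Hodgkin-Huxley gate specification
#'
#' A gate has steady state yInf(V) = 1 / (1 + exp((vHalf - V) / k))
#' (activation for k > 0, inactivation for k < 0) and time constant
#' tau(V) = tauBase + tauAmp * exp(-((V - tauVMid) / tauWidth)^2) in ms
#' (a constant when tauAmp = 0). A gate with \code{instantaneous = TRUE}
#' tracks yInf(V) with no dynamics (used for instantaneous rectification).
#'
#' @param name gate name (unique within its current).
#' @param vHalf half-activation voltage (mV).
#' @param k slope factor (mV); sign selects activation/inactivation.
#' @param exponent gate exponent in the current product (default 1).
#' @param tauBase,tauAmp,tauVMid,tauWidth time-constant parameters (ms, ms,
#'   mV, mV).
#' @param instantaneous logical.
#' @return a gate specification list.
#' @export
gateSpec <- function(name, vHalf, k, exponent = 1,
                     tauBase = 1, tauAmp = 0, tauVMid = 0, tauWidth = 20,
                     instantaneous = FALSE) {
  stopifnot(exponent >= 0, tauBase > 0 || instantaneous)
  list(name = name, vHalf = vHalf, k = k, exponent = exponent,
       tauBase = tauBase, tauAmp = tauAmp, tauVMid = tauVMid,
       tauWidth = tauWidth, instantaneous = instantaneous)
}

#' Ionic current specification
#'
#' A current I = g * prod(gate_i ^ exponent_i) * (V - e) in pA, with g in
#' nS and voltages in mV. A current with no gates is an ohmic background.
#'
#' @param name current name (e.g. "Na", "CaL", "f", "K1").
#' @param g maximal conductance (nS).
#' @param e reversal potential (mV).
#' @param gates list of [gateSpec()] entries.
#' @return a current specification list.
#' @export
currentSpec <- function(name, g, e, gates = list()) {
  stopifnot(g >= 0, is.finite(e))
  list(name = name, g = g, e = e, gates = gates)
}

#' Construct a CellModel
#'
#' @param name model name.
#' @param cm membrane capacitance (pF).
#' @param currents list of [currentSpec()] entries.
#' @param calcium optional SR calcium-handling parameters: \code{vUp}
#'   (uptake scale), \code{kUp} (uptake half-saturation), \code{kRel}
#'   (release rate), \code{kLeak} (leak rate), \code{caiInit},
#'   \code{casrInit}. The subsystem is passive bookkeeping driven by the
#'   L-type activation gate; it carries the SR uptake/release scaling of
#'   model conversion but feeds no current back onto the membrane.
#' @param vInit initial membrane potential (mV); gates start at their
#'   steady state for vInit.
#' @return a [CellModel-class].
#' @export
cellModel <- function(name, cm, currents, calcium = list(), vInit = -75) {
  names(currents) <- vapply(currents, `[[`, character(1), "name")
  new("CellModel", name = name, cm = cm, currents = currents,
      calcium = calcium, vInit = vInit, conversionLog = list())
}

#' @describeIn cellModel maximal conductance of a named current (nS).
#' @param model a CellModel; \code{current} a current name.
#' @param current current name.
#' @export
conductance <- function(model, current) {
  if (!current %in% names(model@currents))
    stop("no current named '", current, "'")
  model@currents[[current]]$g
}

#' @describeIn cellModel membrane capacitance (pF).
#' @export
capacitance <- function(model) model@cm

setMethod("show", "CellModel", function(object) {
  cat("CellModel:", object@name, "- Cm =", object@cm, "pF\n")
  g <- vapply(object@currents, `[[`, numeric(1), "g")
  cat("  currents:",
      paste(sprintf("%s (%.3g nS)", names(g), g), collapse = ", "), "\n")
  if (length(object@calcium))
    cat(sprintf("  SR calcium: vUp %.3g, kRel %.3g\n",
                object@calcium$vUp, object@calcium$kRel))
  if (length(object@conversionLog))
    cat("  converted:", object@conversionLog$direction, "\n")
  invisible(object)
})

# gate steady state / time constant
gateInf <- function(gate, V) 1 / (1 + exp((gate$vHalf - V) / gate$k))
gateTau <- function(gate, V)
  gate$tauBase + gate$tauAmp * exp(-((V - gate$tauVMid) / gate$tauWidth)^2)

# flatten a model into vectors for fast ODE evaluation
compileModel <- function(model) {
  cur <- model@currents
  gV <- vapply(cur, `[[`, numeric(1), "g")
  eV <- vapply(cur, `[[`, numeric(1), "e")
  gates <- list(); gcur <- integer(); dyn <- logical()
  for (ci in seq_along(cur)) for (gt in cur[[ci]]$gates) {
    gates[[length(gates) + 1L]] <- gt
    gcur <- c(gcur, ci)
    dyn <- c(dyn, !gt$instantaneous)
  }
  gn <- length(gates)
  getN <- function(f) vapply(gates, `[[`, numeric(1), f)
  list(
    g = gV, e = eV, nCur = length(cur), curNames = names(cur),
    gCur = gcur, dyn = dyn,
    exponent = if (gn) getN("exponent") else numeric(),
    vHalf = if (gn) getN("vHalf") else numeric(),
    k = if (gn) getN("k") else numeric(),
    tauBase = if (gn) getN("tauBase") else numeric(),
    tauAmp = if (gn) getN("tauAmp") else numeric(),
    tauVMid = if (gn) getN("tauVMid") else numeric(),
    tauWidth = if (gn) getN("tauWidth") else numeric(),
    stateIdx = cumsum(dyn),          # index among dynamic gates
    gateNames = paste(names(cur)[gcur],
                      vapply(gates, `[[`, character(1), "name"), sep = "."),
    hasCa = length(model@calcium) > 0L,
    ca = model@calcium,
    # index of the CaL activation gate (drives SR release), if any
    relGate = {
      i <- which(names(cur)[gcur] == "CaL" &
                   vapply(gates, `[[`, character(1), "name") == "d")
      if (length(i)) i[1L] else 0L
    },
    cm = model@cm
  )
}

# all-gate yInf / tau at scalar or vector V
allGateInf <- function(cm, V) 1 / (1 + exp((cm$vHalf - V) / cm$k))
allGateTau <- function(cm, V)
  cm$tauBase + cm$tauAmp * exp(-((V - cm$tauVMid) / cm$tauWidth)^2)

# per-current total current given V and full gate-value vector
currentValues <- function(cm, V, gateVals) {
  I <- cm$g * (V - cm$e)
  if (length(gateVals)) {
    fac <- gateVals^cm$exponent
    for (j in seq_along(fac)) I[cm$gCur[j]] <- I[cm$gCur[j]] * fac[j]
  }
  I
}

makeDeriv <- function(cm) {
  nDynGates <- sum(cm$dyn)
  function(t, y, parms) {
    V <- y[1L]
    yi <- allGateInf(cm, V)
    gateVals <- yi
    if (nDynGates)
      gateVals[cm$dyn] <- y[1L + cm$stateIdx[cm$dyn]]
    I <- currentValues(cm, V, gateVals)
    dV <- -(sum(I) + parms$iStim) / cm$cm
    dGates <- if (nDynGates)
      ((yi - gateVals) / allGateTau(cm, V))[cm$dyn] else numeric()
    if (cm$hasCa) {
      cai <- y[2L + nDynGates]; casr <- y[3L + nDynGates]
      jUp <- cm$ca$vUp * cai^2 / (cai^2 + cm$ca$kUp^2)
      rel <- if (cm$relGate) gateVals[cm$relGate] else 0
      jRel <- cm$ca$kRel * rel * (casr - cai)
      jLeak <- cm$ca$kLeak * (casr - cai)
      dCa <- c(jRel + jLeak - jUp, jUp - jRel - jLeak)
    } else dCa <- numeric()
    list(c(dV, dGates, dCa))
  }
}

initialState <- function(model, cm) {
  V <- model@vInit
  y <- V
  if (sum(cm$dyn)) {
    yi <- allGateInf(cm, V)
    y <- c(y, yi[cm$dyn])
  }
  if (cm$hasCa) y <- c(y, cm$ca$caiInit, cm$ca$casrInit)
  nm <- c("V", if (sum(cm$dyn)) cm$gateNames[cm$dyn],
          if (cm$hasCa) c("Cai", "CaSR"))
  setNames(y, nm)
}

#' Integrate a cell model
#'
#' Solves dV/dt = -(sum of ionic currents + stimulus)/Cm together with the
#' gate and calcium ODEs using a stiff-capable adaptive solver (lsoda)
#' with output on a fixed grid. Optionally applies square stimulus pulses
#' at a fixed cycle length (integration proceeds segment-by-segment so
#' stimulus edges are exact).
#'
#' @param model a [CellModel-class].
#' @param duration simulated time in seconds (default 20, long enough to
#'   reach a steady state).
#' @param dt output time step in ms (default 0.1).
#' @param pacing \code{NULL} for an unpaced run, or a list with
#'   \code{cycleLength} (ms, default 200), \code{amplitude} (pA, default
#'   -2000) and \code{width} (ms, default 2).
#' @param keepCurrents attach per-current traces (default TRUE).
#' @param rtol,atol solver tolerances.
#' @return data.frame (class \code{"apTrace"}): \code{time} (ms),
#'   \code{vm} (mV), stimulus indicator \code{stim}, gate/calcium states
#'   and, if requested, one column \code{I.<name>} per current (pA).
#' @export
runCell <- function(model, duration = 20, dt = 0.1, pacing = NULL,
                    keepCurrents = TRUE, rtol = 1e-6, atol = 1e-6) {
  validObject(model)
  cm <- compileModel(model)
  deriv <- makeDeriv(cm)
  y <- initialState(model, cm)
  durMs <- duration * 1000
  integrate <- function(y, t0, t1, iStim) {
    times <- seq(t0, t1, by = dt)
    if (tail(times, 1L) < t1) times <- c(times, t1)
    sol <- deSolve::lsoda(y, times, deriv, parms = list(iStim = iStim),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1L] < 0)
      stop("integration failure at t = ", tail(sol[, 1L], 1L), " ms")
    sol
  }
  if (is.null(pacing)) {
    sol <- integrate(y, 0, durMs, 0)
    out <- as.data.frame(sol)
    out$stim <- 0
  } else {
    cl <- pacing$cycleLength %||% 200
    amp <- pacing$amplitude %||% -2000
    width <- pacing$width %||% 2
    pieces <- list()
    t0 <- 0
    while (t0 < durMs - 1e-9) {
      tOn <- min(t0 + width, durMs)
      s1 <- integrate(y, t0, tOn, amp)
      y <- s1[nrow(s1), -1L]
      tOff <- min(t0 + cl, durMs)
      s2 <- integrate(y, tOn, tOff, 0)
      y <- s2[nrow(s2), -1L]
      d1 <- as.data.frame(s1); d1$stim <- amp
      d2 <- as.data.frame(s2[-1L, , drop = FALSE]); d2$stim <- 0
      pieces[[length(pieces) + 1L]] <- rbind(d1, d2)
      t0 <- t0 + cl
    }
    out <- do.call(rbind, pieces)
    out <- out[!duplicated(out$time), ]
  }
  names(out)[1:2] <- c("time", "vm")
  if (any(!is.finite(out$vm)) || max(abs(out$vm)) > 200) {
    bad <- which(!is.finite(out$vm) | abs(out$vm) > 200)[1L]
    stop("membrane potential diverged at t = ", out$time[bad],
         " ms (last state: V = ", signif(out$vm[max(1L, bad - 1L)], 4L), " mV)")
  }
  if (keepCurrents) {
    V <- out$vm
    yi <- vapply(seq_along(cm$vHalf), function(j)
      1 / (1 + exp((cm$vHalf[j] - V) / cm$k[j])), numeric(length(V)))
    if (length(cm$vHalf) == 0L) yi <- matrix(0, length(V), 0L)
    gateVals <- yi
    if (sum(cm$dyn))
      gateVals[, cm$dyn] <- as.matrix(out[, cm$gateNames[cm$dyn], drop = FALSE])
    for (ci in seq_len(cm$nCur)) {
      I <- cm$g[ci] * (V - cm$e[ci])
      for (j in which(cm$gCur == ci))
        I <- I * gateVals[, j]^cm$exponent[j]
      out[[paste0("I.", cm$curNames[ci])]] <- I
    }
  }
  rownames(out) <- NULL
  class(out) <- c("apTrace", "data.frame")
  attr(out, "model") <- model@name
  attr(out, "cm") <- model@cm
  attr(out, "pacing") <- pacing
  out
}
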