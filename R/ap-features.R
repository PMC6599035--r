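# upstroke detection shared by automaticity and feature extraction:
# indices where vm crosses vCross upward with dV/dt above dvdtMin (V/s;
# 1 V/s = 1 mV/ms)
findUpstrokes <- function(time, vm, vCross = -20, dvdtMin = 5) {
  if (length(time) < 3L) return(integer())
  dvdt <- c(NA_real_, diff(vm) / diff(time))
  cross <- which(vm[-1L] >= vCross & vm[-length(vm)] < vCross) + 1L
  cross[!is.na(dvdt[cross]) & dvdt[cross] > dvdtMin]
}

#' Detect spontaneous automaticity in a membrane-potential trace
#'
#' Analyses the final quarter of an unpaced trace: the cell is classified
#' spontaneous when at least two upstrokes (depolarisations crossing
#' -20 mV at more than 5 V/s) occur with a cycle-length coefficient of
#' variation below 10 percent. A window containing exactly one upstroke
#' cannot distinguish slow pacemaking from a solitary event and yields an
#' inconclusive status rather than a boolean.
#'
#' @param trace an \code{apTrace} from [runCell()] (or any data.frame with
#'   \code{time} in ms and \code{vm} in mV). Stimulated samples
#'   (\code{stim != 0}) are masked from upstroke detection.
#' @param windowFraction final fraction of the trace analysed
#'   (default 0.25).
#' @param vCross,dvdtMin upstroke criteria (mV; V/s).
#' @param cvMax maximum cycle-length coefficient of variation
#'   (default 0.1).
#' @return list with \code{spontaneous} (TRUE/FALSE, or NA when
#'   inconclusive), \code{status}, \code{rate} (Hz), \code{cycleLength}
#'   (ms) and the upstroke times.
#' @export
detectAutomaticity <- function(trace, windowFraction = 0.25,
                               vCross = -20, dvdtMin = 5, cvMax = 0.1) {
  t0 <- max(trace$time) - windowFraction * diff(range(trace$time))
  w <- trace[trace$time >= t0, ]
  if (!is.null(w$stim)) {
    up <- findUpstrokes(w$time, w$vm, vCross, dvdtMin)
    up <- up[w$stim[up] == 0]
    # drop upstrokes launched by a stimulus just before the crossing
    if (length(up)) {
      stimT <- w$time[w$stim != 0]
      if (length(stimT))
        up <- up[vapply(w$time[up], function(tt)
          !any(stimT >= tt - 10 & stimT <= tt), logical(1))]
    }
  } else up <- findUpstrokes(w$time, w$vm, vCross, dvdtMin)
  upT <- w$time[up]
  if (length(upT) == 0L)
    return(list(spontaneous = FALSE, status = "quiescent", rate = NA_real_,
                cycleLength = NA_real_, upstrokeTimes = upT))
  if (length(upT) == 1L)
    return(list(spontaneous = NA, status = "inconclusive", rate = NA_real_,
                cycleLength = NA_real_, upstrokeTimes = upT))
  cls <- diff(upT)
  cv <- if (length(cls) > 1L) sd(cls) / mean(cls) else 0
  spont <- cv < cvMax
  list(spontaneous = spont,
       status = if (spont) "spontaneous" else "irregular",
       rate = if (spont) 1000 / mean(cls) else NA_real_,
       cycleLength = if (spont) mean(cls) else NA_real_,
       upstrokeTimes = upT)
}

#' Extract action-potential features from a trace
#'
#' Features are computed on the last two complete action potentials of
#' the trace and averaged: cycle length, maximum diastolic potential
#' (most negative potential between the upstrokes), overshoot (peak
#' potential), APD50/APD90 (duration from the time of maximal upstroke
#' velocity to 50 / 90 percent repolarisation relative to the
#' peak-to-MDP amplitude), maximal upstroke velocity (V/s) and the
#' diastolic depolarisation rate (linear slope over the first half of
#' the diastolic interval, mV/s).
#'
#' @param trace an \code{apTrace} (see [runCell()]).
#' @param vCross,dvdtMin upstroke criteria passed to the detector.
#' @return list of class \code{"apFeatures"}: \code{spontaneous} (logical
#'   or NA; from [detectAutomaticity()] on unpaced traces, FALSE for paced
#'   ones), \code{cycleLength}, \code{mdp}, \code{overshoot},
#'   \code{apd50}, \code{apd90}, \code{dvdtMax},
#'   \code{diastolicDepolarizationRate}.
#' @export
extractFeatures <- function(trace, vCross = -20, dvdtMin = 5) {
  up <- findUpstrokes(trace$time, trace$vm, vCross, dvdtMin)
  if (length(up) < 3L)
    stop("fewer than 2 complete action potentials in the trace")
  # last two complete APs: delimited by the last three upstrokes
  lastUp <- tail(up, 3L)
  perAP <- lapply(1:2, function(i) {
    i1 <- lastUp[i]; i2 <- lastUp[i + 1L]
    seg <- trace[i1:i2, ]
    dvdt <- c(NA_real_, diff(seg$vm) / diff(seg$time))
    # upstroke phase: from segment start until peak
    pk <- which.max(seg$vm)
    dvdtMax <- max(dvdt[2:max(pk, 2L)], na.rm = TRUE)
    tTakeoff <- seg$time[which.max(dvdt[seq_len(max(pk, 2L))])]
    peak <- seg$vm[pk]
    mdpIdx <- pk - 1L + which.min(seg$vm[pk:nrow(seg)])
    mdp <- seg$vm[mdpIdx]
    amp <- peak - mdp
    repol <- function(frac) {
      target <- peak - frac * amp
      post <- seg[pk:nrow(seg), ]
      j <- which(post$vm <= target)[1L]
      if (is.na(j)) return(NA_real_)
      post$time[j] - tTakeoff
    }
    # diastolic depolarisation: first half of MDP -> next upstroke
    dias <- seg[mdpIdx:nrow(seg), ]
    ddr <- if (nrow(dias) > 3L) {
      half <- dias[seq_len(ceiling(nrow(dias) / 2)), ]
      unname(coef(lm(vm ~ time, data = half))[2L]) * 1000  # mV/s
    } else NA_real_
    list(cycleLength = seg$time[nrow(seg)] - seg$time[1L],
         mdp = mdp, overshoot = peak, apd50 = repol(0.5),
         apd90 = repol(0.9), dvdtMax = dvdtMax, ddr = ddr)
  })
  avg <- function(f) mean(vapply(perAP, `[[`, numeric(1), f))
  auto <- if (is.null(attr(trace, "pacing")) ||
              length(attr(trace, "pacing")) == 0L)
    detectAutomaticity(trace)$spontaneous else FALSE
  out <- list(spontaneous = auto,
              cycleLength = avg("cycleLength"),
              mdp = avg("mdp"), overshoot = avg("overshoot"),
              apd50 = avg("apd50"), apd90 = avg("apd90"),
              dvdtMax = avg("dvdtMax"),
              diastolicDepolarizationRate = avg("ddr"))
  class(out) <- "apFeatures"
  out
}

#' @export
print.apFeatures <- function(x, ...) {
  cat("Action-potential features (mean of last two APs)\n")
  cat(sprintf("  spontaneous: %s\n", format(x$spontaneous)))
  cat(sprintf("  cycle length: %.1f ms   MDP: %.1f mV   overshoot: %.1f mV\n",
              x$cycleLength, x$mdp, x$overshoot))
  cat(sprintf("  APD50: %.1f ms   APD90: %.1f ms   dV/dt max: %.1f V/s\n",
              x$apd50, x$apd90, x$dvdtMax))
  cat(sprintf("  diastolic depolarisation rate: %.1f mV/s\n",
              x$diastolicDepolarizationRate))
  invisible(x)
}
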