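#' Shipped mouse atrial myocyte model configuration
#'
#' A reduced Hodgkin-Huxley-ensemble model of a mouse atrial myocyte:
#' 50 pF capacitance; fast Na+ current, L-type Ca2+ current, rapid delayed
#' rectifier, transient outward and ultrarapid K+ currents, inward
#' rectifier, a small background current, and passive SR calcium
#' bookkeeping. The parameterisation is this package's own (the published
#' atrial model it emulates is not redistributed here); it reproduces the
#' defining atrial behaviours: a stable resting potential near -80 mV, no
#' spontaneous activity, and triggered triangular action potentials under
#' pacing.
#'
#' @return a [CellModel-class].
#' @export
atrialCellModel <- function() {
  cellModel(
    "atrial", cm = 50, vInit = -78,
    currents = list(
      currentSpec("Na", g = 400, e = 60, gates = list(
        gateSpec("m", vHalf = -38, k = 7, exponent = 3, tauBase = 0.15),
        gateSpec("h", vHalf = -68, k = -5, tauBase = 0.5, tauAmp = 12,
                 tauVMid = -75, tauWidth = 15)
      )),
      currentSpec("CaL", g = 35, e = 50, gates = list(
        gateSpec("d", vHalf = -12, k = 6, tauBase = 1.5),
        gateSpec("f", vHalf = -30, k = -6, tauBase = 25, tauAmp = 25,
                 tauVMid = -30, tauWidth = 20)
      )),
      currentSpec("Kr", g = 12, e = -85, gates = list(
        gateSpec("x", vHalf = -20, k = 8, tauBase = 40, tauAmp = 160,
                 tauVMid = -30, tauWidth = 30),
        gateSpec("r", vHalf = -15, k = -20, instantaneous = TRUE)
      )),
      currentSpec("to", g = 35, e = -85, gates = list(
        gateSpec("r", vHalf = 0, k = 10, tauBase = 2),
        gateSpec("s", vHalf = -45, k = -5, tauBase = 30, tauAmp = 30,
                 tauVMid = -50, tauWidth = 20)
      )),
      currentSpec("Kur", g = 12, e = -85, gates = list(
        gateSpec("a", vHalf = -10, k = 8, tauBase = 3)
      )),
      currentSpec("K1", g = 7, e = -85, gates = list(
        gateSpec("z", vHalf = -70, k = -8, instantaneous = TRUE)
      )),
      currentSpec("b", g = 0.6, e = -10)
    ),
    calcium = list(vUp = 0.005, kUp = 3e-4, kRel = 0.01, kLeak = 1e-5,
                   caiInit = 1e-4, casrInit = 0.5)
  )
}

# SN-level funny-current and T-type specs inserted during conversion
snFunnySpec <- function(g = 12) {
  currentSpec("f", g = g, e = -30, gates = list(
    gateSpec("y", vHalf = -80, k = -8, tauBase = 120, tauAmp = 500,
             tauVMid = -85, tauWidth = 25)
  ))
}

snCaTSpec <- function(g = 10, vHalfAct = -45) {
  currentSpec("CaT", g = g, e = 45, gates = list(
    gateSpec("d", vHalf = vHalfAct, k = 5, tauBase = 1.5),
    gateSpec("f", vHalf = -67, k = -4.5, tauBase = 8, tauAmp = 12,
             tauVMid = -70, tauWidth = 15)
  ))
}

#' Shipped mouse sinus-node myocyte model configuration
#'
#' A reduced sinus-node cell model with discrete HCN currents: 25 pF
#' capacitance; small fast Na+ current, L- and T-type Ca2+ currents,
#' separate HCN4 and HCN1 funny currents (whole-cell HCN4 conductance
#' 6.255 nS at 1.0 pS unitary conductance), rapid delayed rectifier, a
#' residual transient outward current, a background current, and passive
#' SR calcium bookkeeping. There is no inward-rectifier I_K1 (sinus-node
#' myocytes essentially lack it); the model fires spontaneous pacemaker
#' action potentials.
#'
#' @return a [CellModel-class].
#' @export
sinusNodeCellModel <- function() {
  cellModel(
    "sinusNode", cm = 25, vInit = -60,
    currents = list(
      currentSpec("Na", g = 60, e = 60, gates = list(
        gateSpec("m", vHalf = -38, k = 7, exponent = 3, tauBase = 0.15),
        gateSpec("h", vHalf = -68, k = -5, tauBase = 0.5, tauAmp = 12,
                 tauVMid = -75, tauWidth = 15)
      )),
      currentSpec("CaL", g = 20, e = 50, gates = list(
        gateSpec("d", vHalf = -12, k = 6, tauBase = 1.5),
        gateSpec("f", vHalf = -30, k = -6, tauBase = 25, tauAmp = 25,
                 tauVMid = -30, tauWidth = 20)
      )),
      snCaTSpec(g = 10, vHalfAct = -52),
      {
        s <- snFunnySpec(g = 6.255); s$name <- "fHCN4"; s
      },
      {
        s <- snFunnySpec(g = 1.5); s$name <- "fHCN1"
        s$gates[[1L]]$tauBase <- 60; s$gates[[1L]]$tauAmp <- 150; s
      },
      currentSpec("Kr", g = 8, e = -85, gates = list(
        gateSpec("x", vHalf = -20, k = 8, tauBase = 40, tauAmp = 160,
                 tauVMid = -30, tauWidth = 30),
        gateSpec("r", vHalf = -15, k = -20, instantaneous = TRUE)
      )),
      currentSpec("to", g = 3.5, e = -85, gates = list(
        gateSpec("r", vHalf = 0, k = 10, tauBase = 2),
        gateSpec("s", vHalf = -45, k = -5, tauBase = 30, tauAmp = 30,
                 tauVMid = -50, tauWidth = 20)
      )),
      currentSpec("b", g = 0.3, e = -10)
    ),
    calcium = list(vUp = 0.005, kUp = 3e-4, kRel = 0.01, kLeak = 1e-5,
                   caiInit = 1e-4, casrInit = 0.5)
  )
}

#' Default proteomics-driven conversion table
#'
#' The table of per-current actions applied when converting the atrial
#' model to a sinus-node phenotype (and, inverted, for the reverse
#' conversion): label-free quantification (LFQ) abundance ratios for the
#' currents whose channels were quantified in both tissues, SN-level
#' specifications for the funny and T-type currents absent from the atrial
#' model (with their SN/RA ratios, used when reverse-scaling), the
#' conductance fractions for the currents whose channels were not detected
#' (I_Kur to 0 percent, I_to to 10 percent), the -7 mV shift of the
#' T-type half-activation, SR uptake/release ratios (1: calcium-cycling
#' proteins are not differential between the tissues) and the optional
#' I_K1 ratio mirroring Kir3.1/TASK-1. Ratio values are shipped defaults
#' of this package's model pair, user-overridable and regenerable from a
#' volcano analysis via [computeScalingFromLFQ()].
#'
#' @return a list of class \code{"ScalingTable"}.
#' @export
defaultScalingTable <- function() {
  structure(list(
    ratios = c(Na = 0.4, CaL = 1.2, Kr = 0.8),
    insert = list(f = snFunnySpec(), CaT = snCaTSpec()),
    insertRatio = c(f = 40, CaT = 3),
    fractions = c(Kur = 0, to = 0.1),
    shifts = list(CaT = list(gate = "d", dvHalf = -7)),
    calcium = c(up = 1, rel = 1),
    ik1Ratio = 0.5,
    snCm = 25, atrialCm = 50,
    atrialKur = currentSpec("Kur", g = 12, e = -85, gates = list(
      gateSpec("a", vHalf = -10, k = 8, tauBase = 3)
    ))
  ), class = "ScalingTable")
}

#' @export
print.ScalingTable <- function(x, ...) {
  cat("ScalingTable (SN/RA conversion)\n")
  cat("  LFQ ratios:",
      paste(sprintf("%s = %.3g", names(x$ratios), x$ratios),
            collapse = ", "), "\n")
  cat("  inserted currents:",
      paste(sprintf("%s (ratio %.3g)", names(x$insert), x$insertRatio),
            collapse = ", "), "\n")
  cat("  fractions:",
      paste(sprintf("%s = %.3g", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  cat("  Cm:", x$atrialCm, "->", x$snCm, "pF\n")
  invisible(x)
}

# scale the g of a named current, recording the prior value
.scaleCurrent <- function(model, name, factor, log) {
  if (!name %in% names(model@currents))
    stop("scaling entry for current '", name,
         "' absent from the model")
  log[[paste0("g.", name)]] <- model@currents[[name]]$g
  model@currents[[name]]$g <- model@currents[[name]]$g * factor
  list(model = model, log = log)
}

#' Convert the atrial model to a sinus-node phenotype
#'
#' Applies, in order: the capacitance change 50 -> 25 pF; LFQ-ratio scaling
#' of the Na+, L-type Ca2+ and rapid delayed-rectifier conductances;
#' insertion of the SN-level funny and T-type currents; the -7 mV shift of
#' the T-type half-activation; reduction of I_Kur to 0 percent and I_to to
#' 10 percent; SR uptake/release scaling; and, optionally, I_K1 scaling in
#' line with Kir3.1/TASK-1 (off by default). The edits are recorded in the
#' model's conversion log so the reverse conversion can restore the atrial
#' parameter set exactly.
#'
#' @param atrial the atrial [CellModel-class] (must not already contain
#'   funny or T-type currents).
#' @param scaling a [defaultScalingTable()]-style table.
#' @param scaleIK1 also scale I_K1 by \code{scaling$ik1Ratio}
#'   (default FALSE: most simulations leave I_K1 unchanged).
#' @return the converted [CellModel-class].
#' @export
convertAtrialToSN <- function(atrial, scaling = defaultScalingTable(),
                              scaleIK1 = FALSE) {
  stopifnot(is(atrial, "CellModel"))
  insNames <- names(scaling$insert)
  clash <- intersect(insNames, names(atrial@currents))
  if (length(clash))
    stop("atrial model already contains: ", paste(clash, collapse = ", "))
  model <- atrial
  log <- list(direction = "toSN", cm = atrial@cm, vInit = atrial@vInit,
              name = atrial@name)
  model@cm <- scaling$snCm
  for (nm in names(scaling$ratios)) {
    r <- .scaleCurrent(model, nm, scaling$ratios[[nm]], log)
    model <- r$model; log <- r$log
  }
  for (nm in insNames)
    model@currents[[nm]] <- scaling$insert[[nm]]
  log$inserted <- insNames
  for (nm in names(scaling$shifts)) {
    sh <- scaling$shifts[[nm]]
    gi <- which(vapply(model@currents[[nm]]$gates, `[[`, character(1),
                       "name") == sh$gate)
    model@currents[[nm]]$gates[[gi]]$vHalf <-
      model@currents[[nm]]$gates[[gi]]$vHalf + sh$dvHalf
  }
  for (nm in names(scaling$fractions)) {
    r <- .scaleCurrent(model, nm, scaling$fractions[[nm]], log)
    model <- r$model; log <- r$log
  }
  if (length(model@calcium)) {
    log$calcium <- model@calcium[c("vUp", "kRel")]
    model@calcium$vUp <- model@calcium$vUp * scaling$calcium[["up"]]
    model@calcium$kRel <- model@calcium$kRel * scaling$calcium[["rel"]]
  }
  if (scaleIK1 && "K1" %in% names(model@currents)) {
    r <- .scaleCurrent(model, "K1", scaling$ik1Ratio, log)
    model <- r$model; log <- r$log
  }
  if ("f" %in% insNames) model@vInit <- -60  # start near the SN MDP
  model@name <- paste0(atrial@name, "-to-SN")
  model@conversionLog <- log
  model
}

#' Convert a sinus-node model to an atrial phenotype
#'
#' The reverse conversion. A model produced by [convertAtrialToSN()] is
#' restored exactly from its conversion log. A genuine sinus-node model is
#' converted structurally: capacitance to the atrial value; LFQ-scaled
#' conductances divided by their ratios; funny currents (any current whose
#' name starts with "f") and the T-type current divided by their SN/RA
#' ratios (reduced, not removed, mirroring their low atrial abundance);
#' the T-type activation shifted back; I_to restored from its fraction;
#' I_Kur inserted at the atrial specification; SR scaling inverted; and
#' the atrial inward-rectifier I_K1 inserted (the SN model has none, and
#' without it the converted cell would not rest).
#'
#' @param sn a sinus-node [CellModel-class].
#' @param scaling the same [defaultScalingTable()]-style table.
#' @param atrialIK1 the atrial I_K1 [currentSpec()] to incorporate
#'   (default: the shipped atrial model's).
#' @return the converted [CellModel-class].
#' @export
convertSNToAtrial <- function(sn, scaling = defaultScalingTable(),
                              atrialIK1 = NULL) {
  stopifnot(is(sn, "CellModel"))
  log <- sn@conversionLog
  if (length(log) && identical(log$direction, "toSN")) {
    model <- sn
    model@cm <- log$cm
    model@vInit <- log$vInit
    model@name <- log$name
    for (nm in log$inserted) model@currents[[nm]] <- NULL
    for (f in grep("^g\\.", names(log), value = TRUE))
      model@currents[[sub("^g\\.", "", f)]]$g <- log[[f]]
    # gate shifts were applied to inserted currents, removed above
    if (length(model@calcium) && !is.null(log$calcium)) {
      model@calcium$vUp <- log$calcium$vUp
      model@calcium$kRel <- log$calcium$kRel
    }
    model@conversionLog <- list()
    return(model)
  }
  model <- sn
  model@cm <- scaling$atrialCm
  for (nm in names(scaling$ratios)) {
    if (!nm %in% names(model@currents))
      stop("scaling entry for current '", nm, "' absent from the model")
    model@currents[[nm]]$g <- model@currents[[nm]]$g / scaling$ratios[[nm]]
  }
  funny <- grep("^f", names(model@currents), value = TRUE)
  for (nm in funny)
    model@currents[[nm]]$g <- model@currents[[nm]]$g /
      scaling$insertRatio[["f"]]
  if ("CaT" %in% names(model@currents)) {
    model@currents[["CaT"]]$g <- model@currents[["CaT"]]$g /
      scaling$insertRatio[["CaT"]]
    sh <- scaling$shifts$CaT
    gi <- which(vapply(model@currents$CaT$gates, `[[`, character(1),
                       "name") == sh$gate)
    model@currents$CaT$gates[[gi]]$vHalf <-
      model@currents$CaT$gates[[gi]]$vHalf - sh$dvHalf
  }
  if ("to" %in% names(model@currents) && scaling$fractions[["to"]] > 0)
    model@currents[["to"]]$g <- model@currents[["to"]]$g /
      scaling$fractions[["to"]]
  if (!"Kur" %in% names(model@currents))
    model@currents[["Kur"]] <- scaling$atrialKur
  if (length(model@calcium)) {
    model@calcium$vUp <- model@calcium$vUp / scaling$calcium[["up"]]
    model@calcium$kRel <- model@calcium$kRel / scaling$calcium[["rel"]]
  }
  if (is.null(atrialIK1))
    atrialIK1 <- atrialCellModel()@currents$K1
  if (!"K1" %in% names(model@currents))
    model@currents[["K1"]] <- atrialIK1
  model@vInit <- -78
  model@name <- paste0(sn@name, "-to-atrial")
  model@conversionLog <- list()
  model
}

#' Conductance scaling ratios from a volcano analysis
#'
#' Computes the linear-scale abundance ratio r = 2^log2fc (mean SN over
#' mean RA intensity) per ionic current from differential-analysis results
#' and a protein-to-current mapping. Currents backed by several subunit
#' proteins are pooled by the geometric mean of their linear ratios
#' (equivalently 2^mean(log2fc)). Currents whose proteins are all missing
#' from the results are omitted with a warning.
#'
#' @param volcano a [VolcanoResults-class].
#' @param mapping data.frame with columns \code{protein} and
#'   \code{current}.
#' @return named numeric vector of ratios, usable as the \code{ratios}
#'   element of a scaling table.
#' @export
computeScalingFromLFQ <- function(volcano, mapping) {
  res <- volcanoTable(volcano)
  lfc <- res$log2fc[match(mapping$protein, res$protein)]
  ok <- !is.na(lfc)
  if (any(!ok)) {
    lost <- unique(mapping$current[!ok &
      !mapping$current %in% mapping$current[ok]])
    if (length(lost))
      warning("no quantified protein for current(s): ",
              paste(lost, collapse = ", "), "; omitted")
  }
  sp <- split(lfc[ok], mapping$current[ok])
  vapply(sp, function(v) 2^mean(v), numeric(1))
}
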