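#' @import methods
#' @importFrom stats approx coef lm median na.omit pnorm pt quantile rbinom
#'   rgeom rnorm runif sd setNames var
#' @importFrom utils head read.delim tail write.table combn modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData rowData<- colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ProteomeExperiment: a proteins-by-samples intensity container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] for
#' label-free proteomics. The \code{"lfq"} assay holds log2 LFQ intensities
#' (\code{NA} = not quantified); an optional \code{"ibaq"} assay holds log2
#' iBAQ intensities. \code{colData} must carry a two-level \code{group}
#' factor (tissue of origin, e.g. \code{SN} vs \code{RA}); \code{rowData}
#' carries per-protein peptide counts, reverse/contaminant decoy flags and an
#' isoform-group identifier used to collapse protein isoforms.
#'
#' @slot .Data inherited SummarizedExperiment slots.
#' @seealso [ProteomeExperiment()] for the constructor,
#'   [simulateProteome()] for synthetic instances.
#' @export
setClass("ProteomeExperiment", contains = "SummarizedExperiment")

setValidity("ProteomeExperiment", function(object) {
  msg <- character()
  if (!"lfq" %in% assayNames(object))
    msg <- c(msg, "assay 'lfq' (log2 LFQ intensities) is required")
  cd <- colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (anyNA(cd$group)) {
    msg <- c(msg, "every sample must have a group label")
  }
  rd <- rowData(object)
  for (col in c("peptides", "reverse", "contaminant", "isoformGroup"))
    if (!col %in% colnames(rd))
      msg <- c(msg, sprintf("rowData must contain '%s'", col))
  if ("lfq" %in% assayNames(object)) {
    a <- assay(object, "lfq")
    if (any(is.infinite(a), na.rm = TRUE))
      msg <- c(msg, "lfq intensities must be finite where present")
  }
  if (length(msg)) msg else TRUE
})

#' VolcanoResults: differential-abundance results with permutation FDR
#'
#' Holds the per-protein output of [runVolcano()]: log2 fold change
#' (mean SN minus mean RA), the S0-moderated test statistic, the Student
#' t-test p-value, the significance call at the permutation-derived
#' threshold, the direction of change, per-group imputed-value counts and
#' the post-hoc imputation sanity-check flag.
#'
#' @slot results a [S4Vectors::DataFrame] with one row per protein.
#' @slot config list; the `volcanoConfig()` used.
#' @slot threshold numeric; the |d| cutoff defining significance
#'   (\code{Inf} when nothing passes).
#' @slot nPermutations integer; number of distinct relabelings used.
#' @slot exhaustive logical; whether relabelings were enumerated exhaustively.
#' @slot fdrAtThreshold numeric; estimated FDR at the chosen cutoff.
#' @slot seed integer seed used for permutation sampling.
#' @slot notes character; warning-level conditions recorded during the run.
#' @export
setClass("VolcanoResults",
  representation(
    results = "DataFrame",
    config = "list",
    threshold = "numeric",
    nPermutations = "integer",
    exhaustive = "logical",
    fdrAtThreshold = "numeric",
    seed = "integer",
    notes = "character"
  )
)

setValidity("VolcanoResults", function(object) {
  res <- object@results
  msg <- character()
  need <- c("protein", "log2fc", "d", "p", "significant", "direction")
  miss <- setdiff(need, colnames(res))
  if (length(miss))
    msg <- c(msg, paste("results missing columns:", paste(miss, collapse = ", ")))
  if ("p" %in% colnames(res) && nrow(res) &&
      (min(res$p, na.rm = TRUE) < 0 || max(res$p, na.rm = TRUE) > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (all(c("significant", "direction") %in% colnames(res)) &&
      any(res$significant & res$direction == "none"))
    msg <- c(msg, "significant proteins must have a direction")
  if (length(msg)) msg else TRUE
})

#' MarkovScheme: a single-channel gating model
#'
#' A continuous-time Markov scheme for one ion channel: named states, a
#' list of voltage-dependent transition rates (1/ms as a function of mV) on
#' directed edges, exactly one conducting state, a unitary conductance
#' (pS) and a reversal potential (mV). Two-state C-O schemes describe the
#' HCN pacemaker channels; linear four-state C-O-I1-I2 chains describe
#' channels with inactivation (Cav1.2, Cav3.2, ERG).
#'
#' @slot name channel name.
#' @slot states character vector of state names.
#' @slot rates named list; element \code{"A->B"} is \code{function(V)}
#'   returning the A-to-B rate in 1/ms.
#' @slot conducting name of the single conducting (open) state.
#' @slot gU unitary conductance in pS.
#' @slot eRev reversal potential in mV.
#' @export
setClass("MarkovScheme",
  representation(
    name = "character",
    states = "character",
    rates = "list",
    conducting = "character",
    gU = "numeric",
    eRev = "numeric"
  )
)

setValidity("MarkovScheme", function(object) {
  msg <- character()
  if (length(object@conducting) != 1L ||
      !object@conducting %in% object@states)
    msg <- c(msg, "exactly one conducting state, drawn from 'states'")
  if (length(object@states) < 2L)
    msg <- c(msg, "a scheme needs at least two states")
  edges <- names(object@rates)
  for (e in edges) {
    ft <- strsplit(e, "->", fixed = TRUE)[[1]]
    if (length(ft) != 2L || !all(ft %in% object@states))
      msg <- c(msg, sprintf("malformed edge '%s'", e))
    if (!is.function(object@rates[[e]]))
      msg <- c(msg, sprintf("rate for '%s' must be a function of voltage", e))
  }
  if (!(length(object@gU) == 1L && object@gU > 0))
    msg <- c(msg, "gU must be a single positive conductance (pS)")
  if (length(msg)) msg else TRUE
})

#' VoltageProtocol: a voltage-clamp protocol
#'
#' @slot holdingV holding potential (mV); the channel starts from its
#'   stationary distribution at this voltage.
#' @slot steps data.frame with columns \code{v} (test potential, mV) and
#'   \code{duration} (ms), applied in order within each sweep.
#' @slot sampleDt sampling interval of the recorded current (ms).
#' @export
setClass("VoltageProtocol",
  representation(holdingV = "numeric", steps = "data.frame",
                 sampleDt = "numeric")
)

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  if (!all(c("v", "duration") %in% colnames(object@steps)))
    msg <- c(msg, "steps needs columns 'v' and 'duration'")
  else if (any(object@steps$duration <= 0))
    msg <- c(msg, "step durations must be positive")
  if (object@sampleDt <= 0) msg <- c(msg, "sampleDt must be positive")
  if (length(msg)) msg else TRUE
})

#' SweepSet: simulated unitary-current sweeps
#'
#' @slot sweeps numeric matrix, sweeps in rows, sampled unitary current (pA)
#'   in columns. Each sample is either 0 (closed) or gU * (V - eRev) (open).
#' @slot time sample times (ms) matching the columns.
#' @slot voltage test potential (mV) at each sample time.
#' @slot scheme the [MarkovScheme] simulated.
#' @slot dtMc Monte Carlo time step used (ms).
#' @slot seed integer seed.
#' @export
setClass("SweepSet",
  representation(sweeps = "matrix", time = "numeric", voltage = "numeric",
                 scheme = "MarkovScheme", dtMc = "numeric", seed = "integer")
)

#' CellModel: a Hodgkin-Huxley-ensemble myocyte model
#'
#' A fully config-driven membrane model: membrane capacitance, a list of
#' ionic currents (each with maximal conductance, reversal potential and
#' parametric gates), and an optional passive sarcoplasmic-reticulum
#' calcium-handling subsystem. See [atrialCellModel()] and
#' [sinusNodeCellModel()] for the shipped configurations and
#' [runCell()] for integration.
#'
#' @slot name model name.
#' @slot cm membrane capacitance (pF).
#' @slot currents named list of current specifications (see [currentSpec()]).
#' @slot calcium list of SR parameters (\code{vUp}, \code{kUp}, \code{kRel},
#'   \code{kLeak}, \code{caiInit}, \code{casrInit}) or empty list.
#' @slot vInit initial membrane potential (mV).
#' @slot conversionLog list recording field edits made by model conversion,
#'   sufficient to restore the pre-conversion parameter set.
#' @export
setClass("CellModel",
  representation(name = "character", cm = "numeric", currents = "list",
                 calcium = "list", vInit = "numeric", conversionLog = "list")
)

setValidity("CellModel", function(object) {
  msg <- character()
  if (!(length(object@cm) == 1L && is.finite(object@cm) && object@cm > 0))
    msg <- c(msg, "cm must be a single positive capacitance (pF)")
  if (!is.finite(object@vInit))
    msg <- c(msg, "vInit must be finite")
  nm <- names(object@currents)
  if (length(object@currents) && (is.null(nm) || anyDuplicated(nm)))
    msg <- c(msg, "currents must be uniquely named")
  if (length(msg)) msg else TRUE
})
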