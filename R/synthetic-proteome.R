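#' Configuration for the synthetic proteome generator
#'
#' Collects the parameters of the synthetic two-group (SN vs RA) label-free
#' proteomics experiment: a log-normal intensity matrix with a designated
#' subset of truly differential proteins and abundance-dependent (MNAR)
#' missingness. Defaults emulate the study design the pipeline targets:
#' three biological replicates per tissue, log2 LFQ intensities centred
#' near 25 with ~2 log2 units of between-protein spread, ~0.3 log2 units of
#' replicate noise, and left-censoring concentrated 2 SD below the centre.
#'
#' @param nProteins number of proteins.
#' @param nDifferential number of truly differential proteins
#'   (must be <= nProteins).
#' @param nReplicatesPerGroup replicates per group (default 3).
#' @param log2EffectSize mean log2 shift (SN minus RA) for differential
#'   proteins; split +/- half per group.
#' @param baseMean,baseSd mean and SD (log2) of per-protein base abundances.
#' @param replicateSd within-protein replicate SD (log2), default 0.3.
#' @param mnarMidpoint log2 intensity at which the missingness probability
#'   is 0.5.
#' @param mnarSteepness steepness (1/log2-unit) of the logistic
#'   missingness curve.
#' @param seed integer seed; all generator randomness derives from it
#'   (Mersenne-Twister).
#' @return a list of class \code{"SyntheticProteomeConfig"}.
#' @export
syntheticProteomeConfig <- function(nProteins = 1000L,
                                    nDifferential = 100L,
                                    nReplicatesPerGroup = 3L,
                                    log2EffectSize = 2,
                                    baseMean = 25,
                                    baseSd = 2,
                                    replicateSd = 0.3,
                                    mnarMidpoint = 21,
                                    mnarSteepness = 1,
                                    seed = 1L) {
  cfg <- list(nProteins = as.integer(nProteins),
              nDifferential = as.integer(nDifferential),
              nReplicatesPerGroup = as.integer(nReplicatesPerGroup),
              log2EffectSize = log2EffectSize,
              baseMean = baseMean, baseSd = baseSd,
              replicateSd = replicateSd,
              mnarMidpoint = mnarMidpoint,
              mnarSteepness = mnarSteepness,
              seed = as.integer(seed))
  if (cfg$nProteins <= 0L || cfg$nReplicatesPerGroup <= 0L)
    stop("configuration error: dimensions must be positive")
  if (cfg$nDifferential < 0L || cfg$nDifferential > cfg$nProteins)
    stop("configuration error: nDifferential must lie in [0, nProteins]")
  if (cfg$baseSd <= 0 || cfg$replicateSd <= 0)
    stop("configuration error: SDs must be positive")
  class(cfg) <- "SyntheticProteomeConfig"
  cfg
}

#' Generate a complete synthetic intensity matrix with known ground truth
#'
#' Protein i, sample j is drawn from Normal(mu_i + s_ij, replicateSd^2)
#' with mu_i ~ Normal(baseMean, baseSd^2); differential proteins get a
#' group-dependent shift s_ij = +log2EffectSize/2 in SN and -half in RA,
#' all other proteins s_ij = 0. The matrix is complete (no missingness);
#' use [applyMNAR()] to censor it. The true per-protein log2 fold changes
#' and differential flags are recorded in \code{rowData} and returned in
#' \code{metadata(pe)$groundTruth}.
#'
#' @param config a [syntheticProteomeConfig()].
#' @return a [ProteomeExperiment-class]; \code{metadata(.)$groundTruth} is a
#'   data.frame with \code{protein}, \code{differential}, \code{trueLog2fc}.
#' @examples
#' pe <- simulateProteome(syntheticProteomeConfig(nProteins = 50, seed = 7))
#' @export
simulateProteome <- function(config) {
  stopifnot(inherits(config, "SyntheticProteomeConfig"))
  p <- config$nProteins
  r <- config$nReplicatesPerGroup
  withSeed(config$seed, {
    mu <- rnorm(p, config$baseMean, config$baseSd)
    diffFlag <- rep(FALSE, p)
    if (config$nDifferential > 0L)
      diffFlag[sample.int(p, config$nDifferential)] <- TRUE
    trueLfc <- ifelse(diffFlag, config$log2EffectSize, 0)
    shift <- outer(trueLfc / 2, c(rep(1, r), rep(-1, r)))
    m <- matrix(rnorm(p * 2L * r, mean = mu + shift, sd = config$replicateSd),
                nrow = p)
  })
  ids <- sprintf("protein%05d", seq_len(p))
  dimnames(m) <- list(ids, c(paste0("SN", seq_len(r)), paste0("RA", seq_len(r))))
  pe <- ProteomeExperiment(m, group = rep(c("SN", "RA"), each = r),
                           scale = "log2", ibaq = m)
  rowData(pe)$differential <- diffFlag
  rowData(pe)$trueLog2fc <- trueLfc
  metadata(pe)$groundTruth <- data.frame(protein = ids,
                                         differential = diffFlag,
                                         trueLog2fc = trueLfc)
  metadata(pe)$config <- config
  pe
}

#' Missingness probability of the MNAR censoring curve
#'
#' Logistic, decreasing in intensity: p(x) = 1 / (1 + exp(k * (x - x0)))
#' with midpoint x0 = \code{mnarMidpoint} and steepness k =
#' \code{mnarSteepness}. Low-abundance values are preferentially lost,
#' the standard left-censoring assumption in label-free proteomics.
#'
#' @param x log2 intensity.
#' @param config a [syntheticProteomeConfig()].
#' @return missingness probabilities in [0, 1].
#' @export
mnarProbability <- function(x, config) {
  1 / (1 + exp(config$mnarSteepness * (x - config$mnarMidpoint)))
}

#' Apply abundance-dependent (MNAR) missingness
#'
#' Each entry of the complete matrix is independently set to \code{NA} with
#' probability [mnarProbability()] of its own intensity. Randomness is
#' governed by \code{seed} (default: the config seed + 1, so the censoring
#' stream is distinct from the generation stream but still derived from the
#' config).
#'
#' @param pe a complete [ProteomeExperiment-class].
#' @param config a [syntheticProteomeConfig()].
#' @param seed optional integer override for the censoring stream.
#' @return the ProteomeExperiment with censored \code{lfq} (and
#'   \code{ibaq}, censored at the same positions).
#' @export
applyMNAR <- function(pe, config, seed = NULL) {
  a <- assay(pe, "lfq")
  if (anyNA(a)) stop("applyMNAR expects a complete matrix")
  pMiss <- mnarProbability(a, config)
  stopifnot(all(pMiss >= 0 & pMiss <= 1))
  seed <- seed %||% (config$seed + 1L)
  miss <- withSeed(seed, matrix(runif(length(a)) < pMiss, nrow = nrow(a)))
  a[miss] <- NA_real_
  assay(pe, "lfq") <- a
  if ("ibaq" %in% assayNames(pe)) {
    b <- assay(pe, "ibaq")
    b[miss] <- NA_real_
    assay(pe, "ibaq") <- b
  }
  metadata(pe)$mnarMask <- miss
  pe
}

#' Generate a synthetic iBAQ channel table with known copy numbers
#'
#' Emulates the input of the copy-number module: per-replicate iBAQ
#' intensities for a set of channel proteins whose true per-cell copy
#' numbers are known. The anchor channel (HCN4, tetramer) sets the intensity
#' scale through \code{ibaqAnchor}; channel X receives
#' \code{(trueCount_X * s_X / anchorCount) * ibaqAnchor_r * (1 + noise)},
#' where \code{ibaqAnchor_r} is the anchor's realized intensity in
#' replicate r (replicate-level systematic variation, itself
#' \code{ibaqAnchor * (1 + noise)}) and both noise terms are Gaussian with
#' coefficient of variation \code{cv}. Within-replicate ratios to the
#' anchor therefore carry only the channel's own noise, and inverting
#' through [summarizeReplicates()] recovers \code{trueCounts} exactly at
#' \code{cv = 0} and without bias at \code{cv > 0}.
#'
#' @param stoich stoichiometry data.frame (\code{protein},
#'   \code{subunits}); must contain the anchor with 4 subunits.
#' @param trueCounts named numeric vector of true channels per cell, one
#'   entry per protein in \code{stoich} (the anchor's entry is ignored and
#'   set to \code{anchorCount}).
#' @param anchorCount true anchor copy number (default 6255).
#' @param cv coefficient of variation of the multiplicative replicate noise.
#' @param nReplicates number of replicates (default 3).
#' @param seed integer seed.
#' @param anchor anchor protein id (default \code{"Hcn4"}).
#' @param ibaqAnchor anchor iBAQ intensity on the linear scale.
#' @return data.frame: \code{protein}, \code{subunits}, one \code{ibaq_<i>}
#'   column per replicate, and attribute \code{"trueCounts"}.
#' @export
generateChannelTable <- function(stoich, trueCounts, anchorCount = 6255,
                                 cv = 0.1, nReplicates = 3L, seed = 1L,
                                 anchor = "Hcn4", ibaqAnchor = 1e7) {
  stopifnot(all(c("protein", "subunits") %in% colnames(stoich)))
  ai <- match(anchor, stoich$protein)
  if (is.na(ai) || stoich$subunits[ai] != 4L)
    stop("configuration error: anchor '", anchor,
         "' must be present in the stoichiometry table with 4 subunits")
  trueCounts <- trueCounts[match(stoich$protein, names(trueCounts))]
  names(trueCounts) <- stoich$protein
  trueCounts[anchor] <- anchorCount
  if (anyNA(trueCounts))
    stop("trueCounts must name every protein in the stoichiometry table")
  p <- nrow(stoich)
  base <- (trueCounts * stoich$subunits / anchorCount) * ibaqAnchor
  ib <- withSeed(seed, {
    # the anchor's realized per-replicate intensity is a shared factor
    # (replicate-level systematic variation); channel-specific noise
    # multiplies on top of it, so within-replicate ratios to the anchor
    # carry only the channel's own noise
    anchorFac <- 1 + rnorm(nReplicates, 0, cv)
    noise <- matrix(rnorm(p * nReplicates, 0, cv), p, nReplicates)
    noise[stoich$protein == anchor, ] <- 0
    (base %o% anchorFac) * (1 + noise)
  })
  if (any(ib <= 0))
    stop("noise produced non-positive intensities; reduce cv")
  colnames(ib) <- paste0("ibaq_", seq_len(nReplicates))
  out <- cbind(stoich[, c("protein", "subunits")], as.data.frame(ib))
  attr(out, "trueCounts") <- trueCounts
  out
}
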