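#' Default channel stoichiometry table
#'
#' Subunits per functional channel for the ion-channel proteins of the
#' sinus node. Only HCN4 (tetramer) and Cav1.2 (one pore-forming alpha
#' subunit per channel) are fixed by the analysis convention; the remaining
#' entries follow standard channel biochemistry (tetrameric HCN/Kir/Kv/Ryr,
#' dimeric two-pore K+ channels, monomeric Cav alpha subunits, Serca2 and
#' Ncx1) and are user-overridable. A plain-TSV copy ships in
#' \code{inst/extdata/stoichiometry.tsv}.
#'
#' @return data.frame with columns \code{protein} and \code{subunits}.
#' @export
defaultStoichiometry <- function() {
  data.frame(
    protein = c("Hcn4", "Hcn1", "Cacna1c", "Cacna1h", "Kcnh2",
                "Kcnj3", "Kcnj5", "Kcnj8", "Kcnj11", "Kcnk3",
                "Ryr2", "Atp2a2", "Slc8a1"),
    subunits = c(4L, 4L, 1L, 1L, 4L,
                 4L, 4L, 4L, 4L, 2L,
                 4L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Channels per cell from iBAQ intensities
#'
#' Converts an iBAQ intensity to an absolute per-cell channel count by (1)
#' dividing each protein's iBAQ intensity by the number of subunits
#' constituting one functional channel and (2) normalising to the anchor
#' channel whose absolute copy number is known independently (HCN4,
#' estimated from Markov-chain modelling of the funny current):
#' N_X = N_anchor * (ibaq_X / s_X) / (ibaq_anchor / s_anchor).
#'
#' @param ibaqX linear-scale iBAQ intensity of channel X (> 0).
#' @param sX subunits per channel for X (>= 1).
#' @param ibaqAnchor anchor iBAQ intensity (> 0).
#' @param sAnchor anchor subunits per channel (default 4, HCN4 tetramer).
#' @param nAnchor anchor channels per cell (default 6255).
#' @return estimated channels per cell (real; not rounded).
#' @examples
#' channelsPerCell(2e7, 1, 1e7) # twice the anchor intensity, monomer
#' @export
channelsPerCell <- function(ibaqX, sX, ibaqAnchor, sAnchor = 4,
                            nAnchor = 6255) {
  if (any(!is.finite(ibaqX)) || any(ibaqX <= 0) ||
      any(!is.finite(ibaqAnchor)) || any(ibaqAnchor <= 0))
    stop("non-positive iBAQ intensity: a missing channel must be reported ",
         "as absent, not converted to a count")
  stopifnot(all(sX >= 1), all(sAnchor >= 1))
  nAnchor * (ibaqX / sX) / (ibaqAnchor / sAnchor)
}

#' Summarise replicate-wise channel copy numbers
#'
#' Computes per-replicate copy numbers with replicate-matched anchor
#' normalisation (the ratio to the anchor is formed within each replicate,
#' preserving pairing), then the across-replicate mean and dispersion per
#' channel. Replicates in which the anchor itself was not quantified are
#' excluded with a warning.
#'
#' @param channelTable data.frame with columns \code{protein},
#'   \code{subunits} and one \code{ibaq_<i>} column per replicate
#'   (linear scale; \code{NA} or 0 = not quantified).
#' @param anchor anchor protein id (default "Hcn4").
#' @param nAnchor anchor channels per cell (default 6255).
#' @param dispersion \code{"sd"} (default; matches the error bars of the
#'   copy-number figure) or \code{"sem"}.
#' @return data.frame with \code{protein}, per-replicate \code{count_<i>}
#'   columns, \code{meanCount} and \code{dispersion}.
#' @export
summarizeReplicates <- function(channelTable, anchor = "Hcn4",
                                nAnchor = 6255,
                                dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  ibCols <- grep("^ibaq_", colnames(channelTable), value = TRUE)
  if (length(ibCols) < 2L) stop("at least two replicates are required")
  ai <- match(anchor, channelTable$protein)
  if (is.na(ai)) stop("anchor '", anchor, "' not found")
  ib <- as.matrix(channelTable[, ibCols])
  ib[ib == 0] <- NA_real_
  anchorOk <- is.finite(ib[ai, ]) & ib[ai, ] > 0
  if (!all(anchorOk)) {
    warning("anchor not quantified in replicate(s) ",
            paste(ibCols[!anchorOk], collapse = ", "), "; excluded")
    ib <- ib[, anchorOk, drop = FALSE]
    ibCols <- ibCols[anchorOk]
  }
  if (ncol(ib) < 2L)
    stop("fewer than two replicates with the anchor quantified")
  sX <- channelTable$subunits
  perChan <- ib / sX
  anchorPerChan <- perChan[ai, ]
  counts <- sweep(perChan, 2L, anchorPerChan, "/") * nAnchor
  meanCount <- rowMeans(counts, na.rm = TRUE)
  disp <- apply(counts, 1L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    s <- sd(x)
    if (dispersion == "sem") s / sqrt(length(x)) else s
  })
  out <- data.frame(protein = channelTable$protein,
                    stringsAsFactors = FALSE)
  cc <- as.data.frame(counts)
  colnames(cc) <- sub("^ibaq_", "count_", ibCols)
  out <- cbind(out, cc)
  out$meanCount <- meanCount
  out$dispersion <- disp
  attr(out, "dispersionType") <- dispersion
  out
}
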