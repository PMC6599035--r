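#' Construct a ProteomeExperiment
#'
#' Builds the proteins-by-samples container used throughout the differential
#' abundance pipeline. Intensities must arrive with their scale declared:
#' raw (linear, MaxQuant-style, zeros meaning "not quantified") or already
#' log2-transformed. The scale is never auto-detected from magnitudes;
#' silent auto-detection is a reproducibility hazard.
#'
#' @param lfq numeric matrix, proteins x samples. Raw scale: zeros are
#'   converted to \code{NA} and values log2-transformed. Log2 scale: values
#'   used as-is, missing entries \code{NA}.
#' @param group per-sample group labels (two levels, e.g. "SN"/"RA").
#' @param scale one of \code{"raw"} or \code{"log2"}; mandatory declaration
#'   of the intensity scale of \code{lfq} (and \code{ibaq}).
#' @param peptides per-protein peptide counts (default 2, i.e. passing the
#'   minimum-peptide filter).
#' @param reverse,contaminant per-protein logical decoy/contaminant flags.
#' @param isoformGroup per-protein isoform-group identifier; isoforms of one
#'   canonical protein share a value. Defaults to the protein id itself.
#' @param ibaq optional iBAQ matrix with the same shape and scale handling.
#' @param proteinIds protein identifiers; defaults to rownames of lfq.
#' @return a [ProteomeExperiment-class] with log2 assays.
#' @examples
#' m <- matrix(2^rnorm(12, 25), 2, 6,
#'             dimnames = list(c("P1", "P2"), paste0("s", 1:6)))
#' pe <- ProteomeExperiment(m, group = rep(c("SN", "RA"), each = 3),
#'                          scale = "raw")
#' @export
ProteomeExperiment <- function(lfq, group, scale,
                               peptides = NULL, reverse = NULL,
                               contaminant = NULL, isoformGroup = NULL,
                               ibaq = NULL, proteinIds = NULL) {
  scale <- match.arg(scale, c("raw", "log2"))
  lfq <- as.matrix(lfq)
  if (!is.null(proteinIds)) rownames(lfq) <- proteinIds
  if (is.null(rownames(lfq)))
    rownames(lfq) <- sprintf("protein%04d", seq_len(nrow(lfq)))
  if (length(group) != ncol(lfq))
    stop("'group' must have one label per sample")
  toLog2 <- function(m) {
    if (scale == "raw") {
      if (any(m < 0, na.rm = TRUE)) stop("raw intensities must be >= 0")
      m[m == 0] <- NA_real_
      m <- log2(m)
    }
    m
  }
  lfq <- toLog2(lfq)
  n <- nrow(lfq)
  rd <- DataFrame(
    peptides = as.integer(peptides %||% rep(2L, n)),
    reverse = as.logical(reverse %||% rep(FALSE, n)),
    contaminant = as.logical(contaminant %||% rep(FALSE, n)),
    isoformGroup = as.character(isoformGroup %||% rownames(lfq)),
    row.names = rownames(lfq)
  )
  assays <- list(lfq = lfq)
  if (!is.null(ibaq)) {
    ibaq <- toLog2(as.matrix(ibaq))
    dimnames(ibaq) <- dimnames(lfq)
    assays$ibaq <- ibaq
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = rd,
    colData = DataFrame(group = factor(group), row.names = colnames(lfq))
  )
  new("ProteomeExperiment", se)
}

#' @describeIn ProteomeExperiment per-sample group labels.
#' @param x a ProteomeExperiment.
#' @export
groupLabels <- function(x) colData(x)$group

#' @describeIn ProteomeExperiment per-protein peptide counts.
#' @export
peptideCounts <- function(x) rowData(x)$peptides

#' @describeIn ProteomeExperiment log2 LFQ intensity matrix.
#' @export
lfqIntensities <- function(x) assay(x, "lfq")

#' @describeIn ProteomeExperiment log2 iBAQ intensity matrix (or NULL).
#' @export
ibaqIntensities <- function(x)
  if ("ibaq" %in% assayNames(x)) assay(x, "ibaq") else NULL

setMethod("show", "ProteomeExperiment", function(object) {
  cat("ProteomeExperiment:", nrow(object), "proteins x",
      ncol(object), "samples\n")
  grp <- table(groupLabels(object))
  cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp),
                         collapse = ", "), "\n")
  a <- assay(object, "lfq")
  cat(sprintf("  missing lfq values: %d / %d (%.1f%%)\n",
              sum(is.na(a)), length(a), 100 * mean(is.na(a))))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  invisible(object)
})

#' Accessors for VolcanoResults
#'
#' \code{volcanoTable()} returns the per-protein results DataFrame;
#' \code{significanceThreshold()} the |d| cutoff; \code{nSignificant()} the
#' number of significant proteins (optionally by direction).
#'
#' @param x a [VolcanoResults-class].
#' @return see Details.
#' @export
volcanoTable <- function(x) {
  stopifnot(is(x, "VolcanoResults"))
  x@results
}

#' @rdname volcanoTable
#' @export
significanceThreshold <- function(x) {
  stopifnot(is(x, "VolcanoResults"))
  x@threshold
}

#' @rdname volcanoTable
#' @param direction optionally one of "SN-higher"/"RA-higher" to count one
#'   tail only.
#' @export
nSignificant <- function(x, direction = NULL) {
  res <- volcanoTable(x)
  keep <- res$significant
  if (!is.null(direction)) keep <- keep & res$direction == direction
  sum(keep)
}

setMethod("show", "VolcanoResults", function(object) {
  res <- object@results
  cat("VolcanoResults:", nrow(res), "proteins\n")
  cat(sprintf("  significant: %d (%d SN-higher, %d RA-higher) at FDR q = %g\n",
              sum(res$significant),
              sum(res$significant & res$direction == "SN-higher"),
              sum(res$significant & res$direction == "RA-higher"),
              object@config$fdrQ))
  cat(sprintf("  |d| threshold: %.4g (estimated FDR %.4g)\n",
              object@threshold, object@fdrAtThreshold))
  cat(sprintf("  permutations: %d (%s)\n", object@nPermutations,
              if (object@exhaustive) "exhaustive" else "sampled"))
  if ("flaggedBySanityCheck" %in% colnames(res))
    cat("  flagged by imputation sanity check:",
        sum(res$flaggedBySanityCheck), "\n")
  for (n in object@notes) cat("  note:", n, "\n")
  invisible(object)
})
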