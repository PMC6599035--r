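#' Collapse protein isoforms and drop decoy/contaminant rows
#'
#' Reverse-database and potential-contaminant identifications are removed;
#' within each isoform group only the most abundant isoform (highest summed
#' LFQ intensity across samples, missing values ignored) is retained, so
#' each canonical protein appears once.
#'
#' @param pe a [ProteomeExperiment-class].
#' @return the collapsed ProteomeExperiment.
#' @export
collapseIsoforms <- function(pe) {
  rd <- rowData(pe)
  pe <- pe[!(rd$reverse | rd$contaminant), ]
  a <- assay(pe, "lfq")
  total <- rowSums(a, na.rm = TRUE)
  grp <- rowData(pe)$isoformGroup
  # highest summed intensity wins; first occurrence breaks exact ties
  ord <- order(grp, -total)
  keepIdx <- ord[!duplicated(grp[ord])]
  pe[sort(keepIdx), ]
}

#' Filter proteins on valid values and peptide evidence
#'
#' Retains proteins quantified in at least \code{minValidPerGroup} samples
#' in at least one of the two tissues (SN or RA), and identified with at
#' least \code{minPeptides} peptides.
#'
#' @param pe a [ProteomeExperiment-class].
#' @param minValidPerGroup minimum non-missing values required in one group
#'   (default 3).
#' @param minPeptides minimum peptide count (default 2).
#' @return the filtered ProteomeExperiment.
#' @export
filterProteins <- function(pe, minValidPerGroup = 3L, minPeptides = 2L) {
  gi <- groupIndices(groupLabels(pe))
  if (length(gi$i1) < minValidPerGroup && length(gi$i2) < minValidPerGroup)
    stop("configuration error: fewer than ", minValidPerGroup,
         " samples in both groups")
  a <- assay(pe, "lfq")
  v1 <- rowSums(!is.na(a[, gi$i1, drop = FALSE]))
  v2 <- rowSums(!is.na(a[, gi$i2, drop = FALSE]))
  keep <- (v1 >= minValidPerGroup | v2 >= minValidPerGroup) &
    peptideCounts(pe) >= minPeptides
  pe[keep, ]
}

#' Quantile-normalise intensity columns
#'
#' Replaces each sample's sorted observed values by across-sample mean
#' order statistics, the standard quantile normalisation. Missing entries
#' are ignored and left missing: a sample with k observed values is mapped
#' onto the reference distribution at the k evenly spaced quantile
#' positions of its within-sample ranks (ties receive averaged ranks and
#' interpolated reference values). After normalisation all complete
#' samples share an identical sorted value vector.
#'
#' @param pe a [ProteomeExperiment-class] with at least two samples, or a
#'   plain numeric matrix.
#' @return object of the same type with the \code{lfq} assay normalised.
#' @export
quantileNormalize <- function(pe) {
  m <- if (is(pe, "SummarizedExperiment")) assay(pe, "lfq") else as.matrix(pe)
  if (ncol(m) < 2L) stop("quantile normalisation needs >= 2 samples")
  nObs <- colSums(!is.na(m))
  if (any(nObs == 0L))
    stop("sample(s) with no observed values: ",
         paste(colnames(m)[nObs == 0L], collapse = ", "))
  # reference distribution: mean of order statistics over columns, each
  # column's sorted values interpolated onto a common grid of length nrow
  n <- nrow(m)
  grid <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  refMat <- vapply(seq_len(ncol(m)), function(j) {
    x <- sort(m[, j])
    k <- length(x)
    if (k == n) x
    else approx(x = if (k == 1L) 0.5 else seq(0, 1, length.out = k),
                y = x, xout = grid, rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(refMat)
  out <- m
  for (j in seq_len(ncol(m))) {
    obs <- !is.na(m[, j])
    k <- sum(obs)
    r <- rank(m[obs, j], ties.method = "average")
    pos <- if (k == 1L) 0.5 else (r - 1) / (k - 1)
    out[obs, j] <- approx(grid, ref, xout = pos, rule = 2)$y
  }
  if (is(pe, "SummarizedExperiment")) {
    assay(pe, "lfq") <- out
    pe
  } else out
}

#' Impute left-censored missing values from a downshifted distribution
#'
#' Perseus-style imputation for missing-not-at-random data: each missing
#' entry in sample s is replaced by a draw from
#' Normal(mu_s - downshift * sigma_s, (width * sigma_s)^2), where mu_s and
#' sigma_s are the mean and SD of the sample's observed values. Imputation
#' is performed separately for each sample; observed entries are never
#' altered. Defaults are the Perseus standard settings, width 0.3 and
#' downshift 1.8.
#'
#' @param pe a filtered [ProteomeExperiment-class] (or numeric matrix).
#' @param width width of the imputation distribution as a fraction of the
#'   per-sample SD (default 0.3).
#' @param downshift downshift of its mean in per-sample SD units
#'   (default 1.8).
#' @param seed integer seed for the imputation draws.
#' @return the object with a complete \code{lfq} assay; the logical imputed
#'   mask is stored in \code{assay(., "imputed")} (and returned as attribute
#'   \code{"imputedMask"} for matrix input). The pre-imputation intensities
#'   are kept in \code{assay(., "lfqRaw")}.
#' @export
imputeDownshift <- function(pe, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(width > 0, downshift >= 0)
  m <- if (is(pe, "SummarizedExperiment")) assay(pe, "lfq") else as.matrix(pe)
  mask <- is.na(m)
  out <- m
  withSeed(seed, {
    for (j in seq_len(ncol(m))) {
      obs <- m[!mask[, j], j]
      nMiss <- sum(mask[, j])
      if (nMiss == 0L) next
      if (length(obs) < 2L)
        stop("sample ", colnames(m)[j] %||% j,
             " has fewer than 2 observed values")
      mu <- mean(obs)
      sdv <- sd(obs)
      out[mask[, j], j] <- rnorm(nMiss, mu - downshift * sdv, width * sdv)
    }
  })
  if (is(pe, "SummarizedExperiment")) {
    assay(pe, "lfqRaw") <- m
    assay(pe, "lfq") <- out
    assay(pe, "imputed") <- mask
    metadata(pe)$imputation <- list(width = width, downshift = downshift,
                                    seed = as.integer(seed))
    pe
  } else {
    attr(out, "imputedMask") <- mask
    out
  }
}
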