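#' Volcano analysis configuration
#'
#' Parameters of the S0-moderated permutation-FDR differential analysis.
#' Defaults follow the standard Perseus settings for this design: S0 = 0.1,
#' 750 randomisations, 5 percent FDR, at least three valid values in one
#' tissue and at least two peptides per protein.
#'
#' @param s0 additive stabiliser in the moderated-t denominator (SAM S0).
#' @param nPermutations number of group-label relabelings.
#' @param fdrQ target false-discovery rate.
#' @param minValidPerGroup,minPeptides filter settings, see
#'   [filterProteins()].
#' @return a list of class \code{"VolcanoConfig"}.
#' @export
volcanoConfig <- function(s0 = 0.1, nPermutations = 750L, fdrQ = 0.05,
                          minValidPerGroup = 3L, minPeptides = 2L) {
  stopifnot(s0 >= 0, fdrQ > 0, fdrQ < 1, nPermutations >= 1)
  structure(list(s0 = s0, nPermutations = as.integer(nPermutations),
                 fdrQ = fdrQ, minValidPerGroup = as.integer(minValidPerGroup),
                 minPeptides = as.integer(minPeptides)),
            class = "VolcanoConfig")
}

#' S0-moderated two-sample t statistic
#'
#' Computes d = (mean(x) - mean(y)) / (se + s0), where se is the pooled
#' two-sample standard error, together with the two-sided Student p-value
#' of the unmoderated statistic (the moderation constant S0 damps the
#' significance of low-variance, small-fold-change proteins; it does not
#' enter the reference distribution).
#'
#' @param x,y numeric vectors of log2 intensities, >= 2 values each.
#' @param s0 moderation constant (>= 0).
#' @return list with \code{d}, \code{p}, \code{log2fc}, \code{se}.
#' @examples
#' moderatedT(c(1, 2, 3), c(4, 5, 6), s0 = 0.1)
#' @export
moderatedT <- function(x, y, s0 = 0.1) {
  if (length(x) < 2L || length(y) < 2L)
    stop("at least two values per group are required")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0 && s0 == 0)
    stop("zero variance in both groups with s0 = 0: statistic undefined")
  fc <- mean(x) - mean(y)
  d <- fc / (se + s0)
  p <- if (se == 0) as.numeric(fc == 0)
       else 2 * pt(-abs(fc / se), df = n1 + n2 - 2)
  list(d = d, p = p, log2fc = fc, se = se)
}

# Row-wise moderated statistics for a complete matrix.
# Returns d, t, p, log2fc for group1 (i1) minus group2 (i2).
rowModeratedT <- function(m, i1, i2, s0) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- rowVarsNA(m[, i1, drop = FALSE])
  v2 <- rowVarsNA(m[, i2, drop = FALSE])
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  fc <- m1 - m2
  tt <- fc / se
  p <- 2 * pt(-abs(tt), df = n1 + n2 - 2)
  p[se == 0] <- as.numeric(fc[se == 0] == 0)
  list(d = fc / (se + s0), t = tt, p = p, log2fc = fc)
}

# Distinct relabelings preserving group sizes (columns = indices assigned
# to pseudo-group 1), exhaustive when few, otherwise sampled without
# replacement of distinct assignments. The identity assignment and its
# group-swap mirror reproduce the observed statistics exactly and carry no
# information about the null, so they are excluded; without this exclusion
# a 3-vs-3 design has an estimated-FDR floor of 2/20 = 0.1 and a 5 percent
# cutoff could never be met.
relabelings <- function(n, n1, nPermutations, seed, observed) {
  obsKey <- paste(sort(observed), collapse = ",")
  mirKey <- paste(sort(setdiff(seq_len(n), observed)), collapse = ",")
  keyOf <- function(s) paste(s, collapse = ",")
  total <- choose(n, n1)
  if (total - 2L <= nPermutations) {
    out <- combn(n, n1)
    keys <- apply(out, 2L, keyOf)
    out <- out[, !keys %in% c(obsKey, mirKey), drop = FALSE]
    attr(out, "exhaustive") <- TRUE
    return(out)
  }
  picked <- new.env(hash = TRUE)
  out <- matrix(0L, nrow = n1, ncol = nPermutations)
  got <- 0L
  withSeed(seed, {
    guard <- 0L
    while (got < nPermutations && guard < 100L * nPermutations) {
      guard <- guard + 1L
      s <- sort(sample.int(n, n1))
      key <- keyOf(s)
      if (key %in% c(obsKey, mirKey)) next
      if (is.null(picked[[key]])) {
        picked[[key]] <- TRUE
        got <- got + 1L
        out[, got] <- s
      }
    }
  })
  out <- out[, seq_len(got), drop = FALSE]
  attr(out, "exhaustive") <- FALSE
  out
}

#' Permutation-FDR volcano analysis
#'
#' Tusher-style significance analysis on a complete (imputed) intensity
#' matrix: per-protein |d| statistics are compared with their distribution
#' under random relabelings of the sample group assignments that preserve
#' group sizes. At a cutoff t the FDR is estimated as (mean permuted count
#' of |d*| >= t) / (observed count of |d| >= t); proteins are called
#' significant at the smallest cutoff whose estimated FDR stays at or below
#' \code{fdrQ} (the largest admissible significance set). When the number
#' of distinct relabelings does not exceed \code{nPermutations} they are
#' enumerated exhaustively instead of sampled. The identity relabeling and
#' its group-swap mirror are excluded in either mode (see the methods
#' vignette for why small balanced designs require this).
#'
#' @param pe a complete [ProteomeExperiment-class] (typically after
#'   [imputeDownshift()]), or a complete numeric matrix.
#' @param config a [volcanoConfig()].
#' @param seed integer seed for permutation sampling.
#' @param group group labels (required for matrix input; taken from
#'   \code{colData} otherwise). The SN-like level (named "SN" if present,
#'   else the first level) is the minuend of the fold change.
#' @return a [VolcanoResults-class].
#' @export
runVolcano <- function(pe, config = volcanoConfig(), seed = 1L,
                       group = NULL) {
  if (is(pe, "SummarizedExperiment")) {
    m <- assay(pe, "lfq")
    group <- group %||% groupLabels(pe)
  } else m <- as.matrix(pe)
  if (is.null(group)) stop("group labels are required")
  if (anyNA(m))
    stop("runVolcano requires a complete matrix; impute first")
  group <- factor(group)
  if ("SN" %in% levels(group)) group <- relevel(group, "SN")
  gi <- groupIndices(group)
  notes <- character()
  if (config$nPermutations < 10L)
    notes <- c(notes, sprintf(
      "only %d permutations requested; FDR estimates will be unstable",
      config$nPermutations))

  obs <- rowModeratedT(m, gi$i1, gi$i2, config$s0)
  absd <- abs(obs$d)

  perms <- relabelings(ncol(m), length(gi$i1), config$nPermutations,
                       seed = seed, observed = gi$i1)
  nPerm <- ncol(perms)
  allIdx <- seq_len(ncol(m))
  permAbs <- numeric(nrow(m) * nPerm)
  for (b in seq_len(nPerm)) {
    i1 <- perms[, b]
    db <- rowModeratedT(m, i1, setdiff(allIdx, i1), config$s0)$d
    permAbs[((b - 1L) * nrow(m) + 1L):(b * nrow(m))] <- abs(db)
  }
  permSorted <- sort(permAbs)

  # FDR curve over candidate thresholds = observed |d| values (descending)
  ord <- order(absd, decreasing = TRUE)
  cand <- absd[ord]
  obsCount <- seq_along(cand)
  permTotal <- length(permSorted) - findInterval(cand - 1e-12, permSorted)
  # add-one finite-permutation correction (the observed labeling counts as
  # one more relabeling): without it the per-protein null exceedance
  # probability is underestimated at small permutation counts
  fdr <- pmin(1, (1 + permTotal) / ((nPerm + 1) * obsCount))
  eligible <- which(fdr <= config$fdrQ)
  if (length(eligible)) {
    kStar <- max(eligible)
    threshold <- cand[kStar]
    fdrAt <- fdr[kStar]
    sig <- absd >= threshold
  } else {
    threshold <- Inf
    fdrAt <- NA_real_
    sig <- rep(FALSE, length(absd))
  }

  direction <- rep("none", length(absd))
  direction[sig & obs$log2fc > 0] <- paste0(gi$levels[1L], "-higher")
  direction[sig & obs$log2fc < 0] <- paste0(gi$levels[2L], "-higher")

  res <- DataFrame(
    protein = rownames(m) %||% sprintf("protein%04d", seq_len(nrow(m))),
    log2fc = unname(obs$log2fc), d = unname(obs$d), p = unname(obs$p),
    significant = unname(sig), direction = direction
  )
  if (is(pe, "SummarizedExperiment") && "imputed" %in% assayNames(pe)) {
    im <- assay(pe, "imputed")
    res$imputedSN <- rowSums(im[, gi$i1, drop = FALSE])
    res$imputedRA <- rowSums(im[, gi$i2, drop = FALSE])
  }
  new("VolcanoResults", results = res, config = unclass(config),
      threshold = threshold, nPermutations = as.integer(nPerm),
      exhaustive = attr(perms, "exhaustive"),
      fdrAtThreshold = fdrAt, seed = as.integer(seed), notes = notes)
}

#' Post-hoc imputation sanity check
#'
#' Significant proteins whose call could rest on imputed values (2, 1 or 0
#' quantified values in either tissue) are re-examined against the
#' pre-imputation intensities: a protein is flagged when its raw-intensity
#' SN/RA log2 ratio deviates from the post-imputation ratio by more than
#' \code{maxLog2Deviation}, or when one tissue has no raw evidence at all
#' so the ratio cannot be corroborated. Flags are reported, never silently
#' removed.
#'
#' @param result a [VolcanoResults-class].
#' @param pe the [ProteomeExperiment-class] the result was computed from;
#'   must carry the \code{lfqRaw} and \code{imputed} assays written by
#'   [imputeDownshift()].
#' @param maxLog2Deviation allowed |raw - imputed| log2-ratio deviation
#'   (default 2).
#' @param minValid proteins with fewer quantified values than this in
#'   either group are in scope (default 3, i.e. 2, 1 or 0 valid values).
#' @return the VolcanoResults with columns \code{flaggedBySanityCheck} and
#'   \code{rawLog2fc} added.
#' @export
imputationSanityCheck <- function(result, pe, maxLog2Deviation = 2,
                                  minValid = 3L) {
  stopifnot(is(result, "VolcanoResults"))
  if (!all(c("lfqRaw", "imputed") %in% assayNames(pe)))
    stop("pe must carry 'lfqRaw' and 'imputed' assays (run imputeDownshift)")
  raw <- assay(pe, "lfqRaw")
  res <- result@results
  raw <- raw[match(res$protein, rownames(raw)), , drop = FALSE]
  gi <- groupIndices(groupLabels(pe))
  v1 <- rowSums(!is.na(raw[, gi$i1, drop = FALSE]))
  v2 <- rowSums(!is.na(raw[, gi$i2, drop = FALSE]))
  inScope <- res$significant & (v1 < minValid | v2 < minValid)
  rawFc <- rowMeans(raw[, gi$i1, drop = FALSE], na.rm = TRUE) -
    rowMeans(raw[, gi$i2, drop = FALSE], na.rm = TRUE)
  rawFc[v1 == 0 | v2 == 0] <- NA_real_
  dev <- abs(rawFc - res$log2fc)
  flag <- inScope & (is.na(rawFc) | dev > maxLog2Deviation)
  res$rawLog2fc <- rawFc
  res$flaggedBySanityCheck <- flag
  result@results <- res
  result
}

#' Rank proteins by abundance
#'
#' Ascending abundance ranks (lowest intensity gets rank 1) with tied
#' intensities receiving the mean of the covered ranks, plus the rank
#' percentile rank/N (the most abundant protein has percentile 1).
#'
#' @param ibaq per-protein mean intensities (non-negative; NA allowed and
#'   returned as NA rank).
#' @return data.frame with \code{rank} and \code{percentile}.
#' @export
ibaqRank <- function(ibaq) {
  if (any(ibaq < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  r <- rank(ibaq, ties.method = "average", na.last = "keep")
  n <- sum(!is.na(ibaq))
  data.frame(rank = r, percentile = r / n,
             row.names = names(ibaq) %||% NULL)
}
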