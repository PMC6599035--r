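#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated proteinGroups dialect: protein identifiers in
#' "Protein IDs", peptide counts in "Peptides", decoy and contaminant
#' flags marked "+" in "Reverse" and "Potential contaminant", and
#' per-sample intensities in columns prefixed "LFQ intensity " and
#' "iBAQ ". Zero intensities denote "not quantified" and are read as
#' missing (the MaxQuant convention). The intensity scale must be
#' declared; MaxQuant exports are raw (linear) and are log2-transformed
#' on ingestion.
#'
#' @param path TSV file path.
#' @param group per-sample group labels in the order of the LFQ columns,
#'   or \code{NULL} to derive labels from the leading non-digit part of
#'   each sample name (e.g. "SN1" -> "SN").
#' @param scale declared intensity scale, \code{"raw"} (MaxQuant default)
#'   or \code{"log2"}.
#' @return a [ProteomeExperiment-class].
#' @export
readProteinGroups <- function(path, group = NULL, scale = "raw") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Protein IDs", "Peptides")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  lfqCols <- grep("^LFQ intensity ", colnames(df), value = TRUE)
  if (!length(lfqCols)) stop("missing mandatory column(s): LFQ intensity <sample>")
  samples <- sub("^LFQ intensity ", "", lfqCols)
  if (anyDuplicated(samples))
    stop("duplicated sample name(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  ibaqCols <- paste0("iBAQ ", samples)
  hasIbaq <- all(ibaqCols %in% colnames(df))
  plus <- function(col) {
    if (!col %in% colnames(df)) return(rep(FALSE, nrow(df)))
    x <- trimws(as.character(df[[col]]))
    !is.na(x) & x == "+"
  }
  if (is.null(group)) group <- sub("[0-9]+$", "", samples)
  lfq <- as.matrix(df[, lfqCols])
  colnames(lfq) <- samples
  rownames(lfq) <- make.unique(df[["Protein IDs"]])
  ibaq <- if (hasIbaq) {
    m <- as.matrix(df[, ibaqCols]); colnames(m) <- samples; m
  } else NULL
  ProteomeExperiment(
    lfq, group = group, scale = scale,
    peptides = df[["Peptides"]],
    reverse = plus("Reverse"),
    contaminant = plus("Potential contaminant"),
    isoformGroup = if ("Isoform group" %in% colnames(df))
      df[["Isoform group"]] else NULL,
    ibaq = ibaq
  )
}

#' Write a ProteomeExperiment as a MaxQuant-style table
#'
#' Inverse of [readProteinGroups()]: writes the log2 assays back on the
#' linear scale with missing entries encoded as 0, flags as "+"/"",
#' producing a file the reader ingests losslessly (finite values and
#' missingness round-trip exactly).
#'
#' @param pe a [ProteomeExperiment-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeProteinGroups <- function(pe, path) {
  lfq <- 2^assay(pe, "lfq")
  lfq[is.na(lfq)] <- 0
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   `Protein IDs` = rownames(pe),
                   Peptides = peptideCounts(pe),
                   Reverse = ifelse(rowData(pe)$reverse, "+", ""),
                   `Potential contaminant` =
                     ifelse(rowData(pe)$contaminant, "+", ""),
                   `Isoform group` = rowData(pe)$isoformGroup)
  colnames(lfq) <- paste0("LFQ intensity ", colnames(pe))
  df <- cbind(df, as.data.frame(lfq, check.names = FALSE))
  if ("ibaq" %in% assayNames(pe)) {
    ib <- 2^assay(pe, "ibaq")
    ib[is.na(ib)] <- 0
    colnames(ib) <- paste0("iBAQ ", colnames(pe))
    df <- cbind(df, as.data.frame(ib, check.names = FALSE))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write volcano results as TSV with a JSON run-manifest sidecar
#'
#' @param result a [VolcanoResults-class].
#' @param path output TSV path; the manifest is written next to it as
#'   \code{<path>.manifest.json}.
#' @param inputs optional named character vector of input file paths whose
#'   MD5 checksums enter the manifest.
#' @return \code{path}, invisibly.
#' @export
writeVolcanoResults <- function(result, path, inputs = character()) {
  df <- as.data.frame(volcanoTable(result))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    tool = paste0("pacemakeR ", as.character(utils::packageVersion("pacemakeR"))),
    config = result@config,
    seed = result@seed,
    threshold = result@threshold,
    nPermutations = result@nPermutations,
    inputChecksums = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the proteomics pipeline end to end
#'
#' Executes, in order: synthetic-data generation (or reading an input
#' table), isoform collapse, filtering, quantile normalisation,
#' downshifted imputation, the permutation-FDR volcano analysis with the
#' post-hoc imputation sanity check, and iBAQ-based channel copy-number
#' estimation. All stage outputs are TSV files under \code{outDir}; a
#' run manifest (configuration, seeds, input checksums) is written as
#' \code{manifest.json}. Re-running with an identical configuration and
#' seed reproduces every output byte-for-byte.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed; mandatory, every stochastic stage derives
#'   its stream from it.
#' @param input optional proteinGroups TSV to analyse; when \code{NULL} a
#'   synthetic dataset is generated from \code{synthConfig}.
#' @param synthConfig a [syntheticProteomeConfig()]; its seed is
#'   overridden by \code{seed}.
#' @param volcano a [volcanoConfig()].
#' @param stoichiometry stoichiometry data.frame for the copy-number
#'   stage (default [defaultStoichiometry()]); channels absent from the
#'   data are skipped.
#' @param imputeWidth,imputeDownshiftSd imputation parameters (Perseus
#'   width/downshift).
#' @param nAnchor anchor HCN4 channels per cell for copy numbers.
#' @return named list of output file paths plus the in-memory results,
#'   invisibly.
#' @export
runPipeline <- function(outDir, seed, input = NULL,
                        synthConfig = syntheticProteomeConfig(),
                        volcano = volcanoConfig(),
                        stoichiometry = defaultStoichiometry(),
                        imputeWidth = 0.3, imputeDownshiftSd = 1.8,
                        nAnchor = 6255) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required: stochastic stages refuse to run unseeded")
  seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- "input"
  res <- tryCatch({
    if (is.null(input)) {
      stage <- "simulate"
      synthConfig$seed <- seed
      pe <- applyMNAR(simulateProteome(synthConfig), synthConfig)
      paths$input <- file.path(outDir, "proteinGroups.tsv")
      writeProteinGroups(pe, paths$input)
      pe <- readProteinGroups(paths$input, scale = "raw")
    } else {
      paths$input <- input
      pe <- readProteinGroups(input, scale = "raw")
    }
    stage <- "filter"
    pe <- collapseIsoforms(pe)
    pe <- filterProteins(pe, volcano$minValidPerGroup, volcano$minPeptides)
    stage <- "normalize"
    pe <- quantileNormalize(pe)
    stage <- "impute"
    pe <- imputeDownshift(pe, width = imputeWidth,
                          downshift = imputeDownshiftSd, seed = seed + 1L)
    stage <- "volcano"
    vr <- runVolcano(pe, volcano, seed = seed + 2L)
    vr <- imputationSanityCheck(vr, pe)
    paths$volcano <- file.path(outDir, "volcano.tsv")
    writeVolcanoResults(vr, paths$volcano, inputs = paths$input)
    stage <- "copyNumber"
    cn <- NULL
    if (is.null(input)) {
      # synthetic channel table with plausible per-cell magnitudes
      trueCounts <- c(Hcn4 = 6255, Hcn1 = 2000, Cacna1c = 25000,
                      Cacna1h = 8000, Kcnh2 = 4000, Kcnj3 = 1500,
                      Kcnj5 = 9000, Kcnj8 = 3000, Kcnj11 = 2500,
                      Kcnk3 = 1200, Ryr2 = 16000, Atp2a2 = 6.6e6,
                      Slc8a1 = 1e5)
      keep <- stoichiometry$protein %in% names(trueCounts)
      ct <- generateChannelTable(stoichiometry[keep, , drop = FALSE],
                                 trueCounts, anchorCount = nAnchor,
                                 cv = 0.1, seed = seed + 3L)
      cn <- summarizeReplicates(ct, nAnchor = nAnchor)
    } else {
      ib <- ibaqIntensities(pe)
      if (!is.null(ib)) {
        sn <- grep("^SN", colnames(ib))
        if (length(sn)) ib <- ib[, sn, drop = FALSE]
        hit <- match(stoichiometry$protein, rownames(ib))
        tab <- stoichiometry[!is.na(hit), , drop = FALSE]
        if (nrow(tab) >= 2L && "Hcn4" %in% tab$protein) {
          m <- 2^ib[hit[!is.na(hit)], , drop = FALSE]
          m[is.na(m)] <- 0
          colnames(m) <- paste0("ibaq_", seq_len(ncol(m)))
          cn <- summarizeReplicates(cbind(tab, as.data.frame(m)),
                                    nAnchor = nAnchor)
        }
      }
    }
    if (!is.null(cn)) {
      paths$copyNumber <- file.path(outDir, "copy_numbers.tsv")
      write.table(cn, paths$copyNumber, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    list(pe = pe, volcano = vr, copyNumbers = cn)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         "\ncompleted outputs: ",
         paste(unlist(paths), collapse = ", "), call. = FALSE)
  })
  manifest <- list(
    tool = paste0("pacemakeR ",
                  as.character(utils::packageVersion("pacemakeR"))),
    seed = seed,
    config = list(synthetic = if (is.null(input)) unclass(synthConfig),
                  volcano = unclass(volcano),
                  imputation = list(width = imputeWidth,
                                    downshift = imputeDownshiftSd),
                  nAnchor = nAnchor),
    inputChecksums = as.list(tools::md5sum(unlist(paths["input"]))),
    outputs = lapply(paths[setdiff(names(paths), "input")],
                     function(p) unname(tools::md5sum(p)))
  )
  paths$manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, res))
}
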