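# internal helpers

# Evaluate expr with a locally set Mersenne-Twister seed, restoring the
# caller's RNG state afterwards. seed = NULL runs expr under the current
# stream (used by internal callers that already seeded).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# group-wise column indices for a two-level group factor
groupIndices <- function(group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop("exactly two sample groups are required, got ",
         nlevels(group), call. = FALSE)
  lv <- levels(group)
  list(levels = lv, i1 = which(group == lv[1L]), i2 = which(group == lv[2L]))
}

# rowwise means/vars ignoring NA, without extra dependencies
rowMeansNA <- function(x) rowMeans(x, na.rm = TRUE)

rowVarsNA <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - mu)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
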