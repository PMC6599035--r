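# shared fixtures built in code
suppressPackageStartupMessages(library(SummarizedExperiment))

# small proteome with explicit values and missingness
toyProteome <- function() {
  m <- matrix(c(
    25.0, 25.2, 24.8, 22.1, 22.0, 21.9,   # clear SN-higher
    20.0, 20.1, 19.9, 20.0, 20.2, 19.8,   # null
    18.0, NA,   18.2, NA,   NA,   NA,     # mostly missing in RA
    24.0, 24.1, 23.9, 24.0, 23.8, 24.2    # null
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("P", 1:4),
                  c("SN1", "SN2", "SN3", "RA1", "RA2", "RA3")))
  ProteomeExperiment(m, group = rep(c("SN", "RA"), each = 3),
                     scale = "log2")
}

# a complete matrix with known group labels
completeMatrix <- function(p = 50, seed = 1, sd = 0.3, mean = 25) {
  set.seed(seed)
  m <- matrix(rnorm(p * 6, mean, sd), p, 6,
              dimnames = list(sprintf("p%03d", seq_len(p)),
                              c("SN1", "SN2", "SN3", "RA1", "RA2", "RA3")))
  m
}

toyGroups <- rep(c("SN", "RA"), each = 3)

# independent brute-force moderated statistic (direct single formula)
oracleD <- function(x, y, s0) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  (mean(x) - mean(y)) / (se + s0)
}

# simple two-state analytic occupancy p_open(t) at fixed V from p0
analyticTwoState <- function(alpha, beta, p0, t) {
  pInf <- alpha / (alpha + beta)
  tau <- 1 / (alpha + beta)
  pInf + (p0 - pInf) * exp(-t / tau)
}

# literal per-step Bernoulli chain, the discrete-time oracle for the
# geometric-sojourn simulation engine (two-state, fixed voltage)
oracleBernoulliChain <- function(pOpenStep, pCloseStep, nSteps, state0) {
  st <- state0   # 1 = closed, 2 = open
  out <- integer(nSteps)
  for (i in seq_len(nSteps)) {
    u <- runif(1)
    if (st == 1L && u < pOpenStep) st <- 2L
    else if (st == 2L && u < pCloseStep) st <- 1L
    out[i] <- st
  }
  out
}

# synthetic triangular action-potential train: upstroke is a fast linear
# rise, repolarisation a slow linear fall; closed-form APDs
triangularAPTrain <- function(nAP = 4, clMs = 200, peak = 20, mdp = -60,
                              riseMs = 2, fallMs = 100, dt = 0.1) {
  oneAP <- function() {
    tUp <- seq(0, riseMs, by = dt)
    vUp <- mdp + (peak - mdp) * tUp / riseMs
    tDown <- seq(dt, fallMs, by = dt)
    vDown <- peak - (peak - mdp) * tDown / fallMs
    nRest <- round((clMs - riseMs - fallMs) / dt)
    c(vUp, vDown, rep(mdp, nRest))
  }
  v <- rep(oneAP(), nAP)
  data.frame(time = seq_along(v) * dt, vm = v, stim = 0)
}
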