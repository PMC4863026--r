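# Deterministic in-code fixtures shared across test files.

# small climate grid with N(0,1) white-noise variables
tinyGrid <- function(ncols = 8, nrows = 8, vars = c("v1", "v2"), seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(ncols * nrows * length(vars)), ncol = length(vars),
                 dimnames = list(NULL, vars))
  ClimateGrid(vals, ncols, nrows)
}

admFromMatrix <- function(x, y) {
  new("AlignedDesignMatrix", features = as.matrix(x),
      presence = as.integer(y),
      cell = seq_len(nrow(x)), recordId = seq_len(nrow(x)), nDropped = 0L)
}

# linearly separable toy design: presence iff v1 > 0, with a margin
separableDesign <- function(n = 100, seed = 1) {
  set.seed(seed)
  v1 <- c(runif(n / 2, 0.5, 3), runif(n / 2, -3, -0.5))
  v2 <- rnorm(n)
  admFromMatrix(cbind(v1 = v1, v2 = v2), as.integer(v1 > 0))
}

# design sampled from a known niche: probabilistic labels, both classes
nicheDesign <- function(n = 200, seed = 1, gridSeed = seed + 500,
                        tolerance = 0.4) {
  g <- generateLandscape(landscapeConfig(24, 24, data.frame(
    name = c("v1", "v2"), corLength = 3, mean = 0, sd = 1),
    seed = gridSeed))
  niche <- nicheSpec(c(v1 = 0, v2 = 0), tolerance = tolerance,
                     weight = 1, maxSuitability = 0.95)
  occ <- sampleOccurrences(g, niche, samplingSpec(n / 2, n / 2, "A", seed))
  list(grid = g, adm = extractFeatures(g, occ), occ = occ)
}

# independent brute-force oracle for the two-sided Wilcoxon-Mann-Whitney
# exact p-value: enumerate all assignments of pooled ranks to group A and
# apply the same two-sided doubling rule R uses.
bruteForceRanksumP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  sets <- combn(na + nb, na)
  u <- apply(sets, 2, function(s) sum(rk[s]) - na * (na + 1) / 2)
  uObs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  p <- if (uObs > na * nb / 2) 2 * mean(u >= uObs) else 2 * mean(u <= uObs)
  min(p, 1)
}

# per-cell loop oracles for the overlap statistics
loopSchoenerD <- function(px, py) {
  acc <- 0
  for (i in seq_along(px)) acc <- acc + abs(px[i] - py[i])
  1 - acc / 2
}
loopHellingerI <- function(px, py) {
  acc <- 0
  for (i in seq_along(px)) acc <- acc + (sqrt(px[i]) - sqrt(py[i]))^2
  1 - acc / 2
}
loopPrintedI <- function(px, py) {
  acc <- 0
  for (i in seq_along(px)) acc <- acc + (px[i] - py[i])^2
  1 - acc / 2
}

randomNormalized <- function(n) {
  v <- runif(n)
  v / sum(v)
}
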