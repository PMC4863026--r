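# Synthetic landscapes with known ground truth: spatially autocorrelated,
# cross-correlated climate fields; Gaussian-product niches; rejection-sampled
# presence/absence records.

#' Configure a synthetic climate landscape
#'
#' Describes a lattice of climate variables. Each variable is a spatially
#' autocorrelated Gaussian random field (Gaussian-filtered white noise on a
#' torus; the filter SD is the correlation length). Cross-variable
#' correlation is imposed by eigendecomposition mixing of the filtered,
#' standardized fields before marginal scaling, so the realized marginals
#' match `mean`/`sd` exactly and pairwise correlations approximate
#' `crossCorrelation`.
#'
#' @param width,height grid dimensions in cells (each at least 8).
#' @param variables data.frame with columns `name`, `corLength` (spatial
#'   correlation length in cells; 0 = white noise), `mean`, `sd`.
#' @param crossCorrelation symmetric positive semi-definite correlation
#'   matrix among variables (unit diagonal); default identity.
#' @param seed integer seed.
#' @return A validated `LandscapeConfig` (classed list).
#' @seealso [generateLandscape()]
#' @export
#' @examples
#' cfg <- landscapeConfig(32, 32, data.frame(
#'   name = c("dd5", "MAP"), corLength = 4, mean = c(800, 600),
#'   sd = c(150, 200)), crossCorrelation = matrix(c(1, .5, .5, 1), 2))
landscapeConfig <- function(width, height, variables,
                            crossCorrelation = NULL, seed = 1L) {
  if (width < 8 || height < 8)
    stop("grid dimensions must be at least 8 x 8 cells")
  variables <- as.data.frame(variables)
  need <- c("name", "corLength", "mean", "sd")
  if (!all(need %in% names(variables)))
    stop("variables needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(variables$name))
    stop("variable names must be unique")
  if (any(variables$sd <= 0)) stop("marginal sd must be positive")
  k <- nrow(variables)
  if (is.null(crossCorrelation)) crossCorrelation <- diag(k)
  crossCorrelation <- as.matrix(crossCorrelation)
  if (!isTRUE(all.equal(crossCorrelation, t(crossCorrelation))) ||
      !isTRUE(all.equal(diag(crossCorrelation), rep(1, k))))
    stop("crossCorrelation must be symmetric with unit diagonal")
  ev <- eigen(crossCorrelation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "crossCorrelation is not positive semi-definite (min eigenvalue %.3g): %s",
      min(ev),
      paste(utils::capture.output(print(crossCorrelation)), collapse = " / ")))
  structure(list(width = as.integer(width), height = as.integer(height),
                 variables = variables, crossCorrelation = crossCorrelation,
                 seed = as.integer(seed)),
            class = "LandscapeConfig")
}

#' Specify a ground-truth niche response
#'
#' The generative niche is a weighted Gaussian product: suitability at a
#' cell with climate values \eqn{x_v} is
#' \deqn{s(x) = m \exp\left(-\tfrac12 \sum_v w_v
#'   \left(\frac{x_v - o_v}{\tau_v}\right)^2\right),}
#' where \eqn{o_v} is the optimum, \eqn{\tau_v} the tolerance (SD in
#' variable units), \eqn{w_v \ge 0} the weight and \eqn{m} the maximum
#' suitability attained at the joint optimum. Values always lie in
#' \eqn{[0, m] \subseteq [0, 1]}.
#'
#' @param optimum named numeric: per-variable optimum, in variable units.
#' @param tolerance named numeric: per-variable tolerance SD (positive);
#'   recycled if unnamed scalar.
#' @param weight named numeric: nonnegative weights, not all zero;
#'   recycled if unnamed scalar.
#' @param maxSuitability suitability at the joint optimum, in (0, 1].
#' @return A validated `NicheSpec` (classed list).
#' @export
nicheSpec <- function(optimum, tolerance = 1, weight = 1,
                      maxSuitability = 1) {
  vars <- names(optimum)
  if (is.null(vars)) stop("optimum must be a named vector")
  expand <- function(v) {
    if (is.null(names(v))) {
      if (length(v) == 1L) v <- rep(v, length(vars))
      if (length(v) != length(vars))
        stop("tolerance/weight must be scalar, match the optimum's length, or be named")
      v <- setNames(v, vars)
    }
    if (!all(vars %in% names(v)))
      stop("tolerance/weight must cover all optimum variables")
    v[vars]
  }
  tolerance <- expand(tolerance); weight <- expand(weight)
  if (any(tolerance <= 0)) stop("tolerances must be positive")
  if (any(weight < 0)) stop("weights must be nonnegative")
  if (maxSuitability <= 0 || maxSuitability > 1)
    stop("maxSuitability must be in (0, 1]")
  structure(list(optimum = optimum, tolerance = tolerance, weight = weight,
                 maxSuitability = maxSuitability),
            class = "NicheSpec")
}

#' Specify occurrence sampling
#'
#' @param nPresence,nAbsence numbers of presence and absence records to
#'   draw (nonnegative, not both zero).
#' @param clusterLabel label attached to presence records (absences carry
#'   `"none"`).
#' @param seed integer seed.
#' @return A validated `SamplingSpec` (classed list).
#' @export
samplingSpec <- function(nPresence, nAbsence, clusterLabel = "none",
                         seed = 1L) {
  if (nPresence < 0 || nAbsence < 0) stop("counts must be nonnegative")
  if (nPresence + nAbsence == 0) stop("nPresence + nAbsence must be positive")
  structure(list(nPresence = as.integer(nPresence),
                 nAbsence = as.integer(nAbsence),
                 clusterLabel = as.character(clusterLabel),
                 seed = as.integer(seed)),
            class = "SamplingSpec")
}

# Gaussian smoothing of a matrix on a torus via FFT; sigma in cells.
.smoothTorus <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  g1 <- function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    exp(-d^2 / (2 * sigma^2))
  }
  k <- outer(g1(nr), g1(nc))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / length(m)
}

#' Generate a synthetic climate grid
#'
#' Realizes the random fields described by a [landscapeConfig()]: per
#' variable, white noise is Gaussian-filtered on a torus at the variable's
#' correlation length and standardized; the standardized fields are then
#' mixed through the eigendecomposition of the cross-correlation matrix and
#' rescaled to the requested marginal mean/SD (realized marginals are exact
#' by construction; realized cross-correlations are approximate).
#'
#' @param config a `LandscapeConfig`.
#' @return A [ClimateGrid-class]; identical for identical configs (seeded).
#' @export
#' @examples
#' cfg <- landscapeConfig(16, 16, data.frame(
#'   name = c("a", "b"), corLength = 2, mean = 0, sd = 1))
#' g <- generateLandscape(cfg)
generateLandscape <- function(config) {
  stopifnot(inherits(config, "LandscapeConfig"))
  v <- config$variables
  k <- nrow(v)
  nc <- config$width; nr <- config$height
  ncell <- nc * nr
  set.seed(config$seed)
  z <- matrix(0, ncell, k)
  for (j in seq_len(k)) {
    # field stored row-major from lower-left: matrix (nrows x ncols) then t()
    w <- matrix(rnorm(ncell), nr, nc)
    f <- .smoothTorus(w, v$corLength[j])
    f <- as.numeric(t(f))          # row-major: y-major over rows of f
    z[, j] <- (f - mean(f)) / sd(f)
  }
  e <- eigen(config$crossCorrelation, symmetric = TRUE)
  a <- diag(sqrt(pmax(e$values, 0)), k) %*% t(e$vectors)
  mixed <- z %*% a
  out <- matrix(0, ncell, k, dimnames = list(NULL, v$name))
  for (j in seq_len(k)) {
    col <- mixed[, j]
    s <- sd(col)
    col <- if (s > 0) (col - mean(col)) / s else col * 0
    out[, j] <- col * v$sd[j] + v$mean[j]
  }
  ClimateGrid(out, nc, nr)
}

.suitabilityValues <- function(grid, niche) {
  vars <- names(niche$optimum)
  missing <- setdiff(vars, variableNames(grid))
  if (length(missing))
    stop(sprintf("unknown niche variable(s) %s; grid has: %s",
                 paste(missing, collapse = ", "),
                 paste(variableNames(grid), collapse = ", ")))
  x <- grid@values[, vars, drop = FALSE]
  zc <- sweep(x, 2, niche$optimum, "-")
  zc <- sweep(zc, 2, niche$tolerance, "/")
  q <- as.numeric((zc^2) %*% niche$weight)
  niche$maxSuitability * exp(-0.5 * q)
}

#' Evaluate a ground-truth suitability surface
#'
#' Applies a [nicheSpec()] Gaussian-product response to every cell of a
#' climate grid. No-data cells propagate as no-data.
#'
#' @param grid a [ClimateGrid-class].
#' @param niche a `NicheSpec`.
#' @return A [PredictionSurface-class] with values in \[0, 1\].
#' @export
suitabilitySurface <- function(grid, niche) {
  stopifnot(is(grid, "ClimateGrid"), inherits(niche, "NicheSpec"))
  .surfaceLike(grid, .suitabilityValues(grid, niche))
}

#' Sample presence/absence records from a ground-truth niche
#'
#' Rejection sampling over grid cells: candidate cells are drawn uniformly
#' and accepted with probability equal to the cell's suitability (presences)
#' or one minus it (absences). Because acceptance is stochastic, labels are
#' noisy — presences can occur in marginal habitat — so fitted models cannot
#' be trivially perfect. Records take their cell-centre coordinates.
#'
#' The realized acceptance rates are attached as attribute
#' `acceptanceRate` (`presence`, `absence`) for diagnostics.
#'
#' @param grid a [ClimateGrid-class].
#' @param niche a `NicheSpec` (or a [PredictionSurface-class] of
#'   suitabilities on the same grid).
#' @param spec a `SamplingSpec`.
#' @return An [OccurrenceSet-class] with `nPresence + nAbsence` records,
#'   presences first, in draw order.
#' @export
sampleOccurrences <- function(grid, niche, spec) {
  stopifnot(is(grid, "ClimateGrid"), inherits(spec, "SamplingSpec"))
  suit <- if (is(niche, "PredictionSurface")) niche@values
          else .suitabilityValues(grid, niche)
  valid <- which(!is.na(suit))
  if (!length(valid)) stop("grid has no valid cells")
  sv <- suit[valid]
  if (spec$nPresence > 0 && all(sv == 0))
    stop(sprintf("cannot sample %d presences: suitability is identically zero",
                 spec$nPresence))
  if (spec$nAbsence > 0 && all(sv == 1))
    stop(sprintf("cannot sample %d absences: suitability is identically one",
                 spec$nAbsence))
  set.seed(spec$seed)
  draw <- function(n, accProb) {
    cells <- integer(0); tries <- 0
    while (length(cells) < n) {
      batch <- max(1000L, ceiling((n - length(cells)) / max(mean(accProb), 1e-6)))
      cand <- sample.int(length(valid), batch, replace = TRUE)
      keep <- runif(batch) < accProb[cand]
      cells <- c(cells, valid[cand[keep]])
      tries <- tries + batch
    }
    list(cells = cells[seq_len(n)],
         rate = if (tries > 0) length(cells) / tries else NA_real_)
  }
  pres <- draw(spec$nPresence, sv)
  abs_ <- draw(spec$nAbsence, 1 - sv)
  xy <- cellCoordinates(grid)
  cells <- c(pres$cells, abs_$cells)
  occ <- OccurrenceSet(xy[cells, 1L], xy[cells, 2L],
                       c(rep(1L, spec$nPresence), rep(0L, spec$nAbsence)),
                       c(rep(spec$clusterLabel, spec$nPresence),
                         rep("none", spec$nAbsence)))
  attr(occ, "acceptanceRate") <- c(presence = pres$rate, absence = abs_$rate)
  occ
}

#' Build a two-cluster niche-divergence scenario
#'
#' Emulates a species split into two population clusters ("NC" and "SC")
#' whose climatic optima differ by `divergence` tolerance units along the
#' designated variable(s), on a shared landscape. Absences are sampled once
#' from the complement of the combined suitability (the landscape is
#' unsuitable for the species as a whole) and shared between the clusters,
#' mirroring study designs in which each regional presence set is paired
#' with all range-wide absences.
#'
#' Defaults define the package's reference study conditions: four climate
#' variables (two of which drive the niche), correlation length 12 cells,
#' pairwise cross-correlation 0.3, niche tolerance 0.4 SD, maximum
#' suitability 0.95, 1000 presences per cluster and 2000 shared absences
#' (absences roughly equal to total presences). With `divergence = 0` both
#' clusters are sampled from one and the same niche.
#'
#' @param divergence separation of the two optima in tolerance units
#'   (nonnegative).
#' @param width,height grid dimensions in cells.
#' @param nVars number of climate variables (named `v1`, `v2`, ...).
#' @param corLength spatial correlation length in cells.
#' @param crossCor pairwise correlation among all variables.
#' @param tolerance niche tolerance, in marginal-SD units.
#' @param maxSuitability suitability at each cluster's optimum.
#' @param nPresence presences per cluster.
#' @param nAbsence shared absences.
#' @param activeVars indices of variables the niche responds to (weight 1;
#'   all others weight 0).
#' @param divergeOn index of the variable along which the optima separate
#'   (must be active).
#' @param seed master seed; stage seeds are derived via [seedForStage()].
#' @return A list with elements `grid` ([ClimateGrid-class]),
#'   `occ` (combined [OccurrenceSet-class]: NC + SC presences + shared
#'   absences), `occNC`/`occSC` (each cluster's presences plus the shared
#'   absences), `nicheNC`, `nicheSC`, and `config`.
#' @export
#' @examples
#' sc <- makeTwoClusterScenario(4, width = 32, height = 32,
#'                              nPresence = 50, nAbsence = 100, seed = 7)
#' sc$occ
makeTwoClusterScenario <- function(divergence,
                                   width = 128L, height = 128L,
                                   nVars = 4L, corLength = 12,
                                   crossCor = 0.3, tolerance = 0.4,
                                   maxSuitability = 0.95,
                                   nPresence = 1000L, nAbsence = 2000L,
                                   activeVars = c(1L, 2L), divergeOn = 1L,
                                   seed = 1L) {
  if (divergence < 0) stop("divergence must be nonnegative")
  if (!divergeOn %in% activeVars)
    stop("divergeOn must be one of the active variables")
  vn <- paste0("v", seq_len(nVars))
  cc <- matrix(crossCor, nVars, nVars); diag(cc) <- 1
  cfg <- landscapeConfig(width, height,
                         data.frame(name = vn, corLength = corLength,
                                    mean = 0, sd = 1),
                         crossCorrelation = cc,
                         seed = seedForStage(seed, "landscape"))
  grid <- generateLandscape(cfg)
  w <- setNames(rep(0, nVars), vn); w[activeVars] <- 1
  opt <- setNames(rep(0, nVars), vn)
  shift <- divergence * tolerance / 2
  optNC <- opt; optNC[divergeOn] <- -shift
  optSC <- opt; optSC[divergeOn] <- +shift
  tol <- setNames(rep(tolerance, nVars), vn)
  nicheNC <- nicheSpec(optNC, tol, w, maxSuitability)
  nicheSC <- nicheSpec(optSC, tol, w, maxSuitability)
  presNC <- presences(sampleOccurrences(grid, nicheNC,
    samplingSpec(nPresence, 0, "NC", seedForStage(seed, "sample:NC"))))
  presSC <- presences(sampleOccurrences(grid, nicheSC,
    samplingSpec(nPresence, 0, "SC", seedForStage(seed, "sample:SC"))))
  sNC <- .suitabilityValues(grid, nicheNC)
  sSC <- .suitabilityValues(grid, nicheSC)
  combined <- .surfaceLike(grid, pmax(sNC, sSC))
  absShared <- absences(sampleOccurrences(grid, combined,
    samplingSpec(0, nAbsence, "none", seedForStage(seed, "sample:absence"))))
  list(grid = grid,
       occ = bindOccurrences(presNC, presSC, absShared),
       occNC = bindOccurrences(presNC, absShared),
       occSC = bindOccurrences(presSC, absShared),
       nicheNC = nicheNC, nicheSC = nicheSC, config = cfg)
}
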