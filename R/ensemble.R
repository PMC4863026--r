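# Repeated-split training, true-skill-statistic evaluation, gating, and
# committee averaging.

#' Stratified train/test split
#'
#' Splits an aligned design by class so that presences and absences appear
#' in the train and test portions at the input proportions. The training
#' total is `round(trainFraction * n)`, allocated to the classes by
#' largest remainder and clamped so both portions keep at least one record
#' per class. The split is an exact partition: no overlap, union equals
#' the input.
#'
#' @param data an [AlignedDesignMatrix-class] with both classes, at least
#'   two records per class.
#' @param trainFraction fraction of records used for training, in (0, 1);
#'   the conventional choice is 0.8 (an 80/20 split).
#' @param seed integer seed.
#' @return List with elements `train` and `test`
#'   ([AlignedDesignMatrix-class]).
#' @export
splitData <- function(data, trainFraction = 0.8, seed = 1L) {
  stopifnot(is(data, "AlignedDesignMatrix"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  y <- data@presence
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L)
    stop(sprintf("need at least 2 records per class to split (%d presences, %d absences)",
                 n1, n0))
  set.seed(seed)
  nc <- c(`0` = n0, `1` = n1)
  base <- floor(trainFraction * nc)
  target <- floor(trainFraction * (n0 + n1) + 0.5)
  extra <- target - sum(base)
  if (extra > 0) {
    take <- order(trainFraction * nc - base, decreasing = TRUE)[seq_len(extra)]
    base[take] <- base[take] + 1L
  }
  base <- pmin(pmax(base, 1L), nc - 1L)
  trainIdx <- logical(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    trainIdx[sample(idx, base[as.character(cls)])] <- TRUE
  }
  list(train = data[trainIdx], test = data[!trainIdx])
}

#' Evaluate binary predictions with the true skill statistic
#'
#' Binarizes probabilistic predictions at a threshold (classifying
#' `prediction >= threshold` as presence) and reports sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and TSS = sensitivity +
#' specificity - 1. TSS is 1 for perfect correspondence between predicted
#' and observed presences/absences and 0 for none.
#'
#' @param predictions numeric probabilities in \[0, 1\].
#' @param labels 0/1 observed labels, both classes present.
#' @param threshold `"maximize"` (default: the threshold among the observed
#'   prediction values that maximizes TSS, ties resolved to the lowest
#'   threshold) or a fixed numeric threshold in (0, 1).
#' @return List of class `tssEvaluation`: `sensitivity`, `specificity`,
#'   `tss`, `threshold`, `nTest`.
#' @export
#' @examples
#' evaluateTSS(c(.9, .8, .2, .1), c(1, 1, 0, 0), threshold = 0.5)$tss  # 1
evaluateTSS <- function(predictions, labels, threshold = "maximize") {
  labels <- as.integer(labels)
  if (length(predictions) != length(labels))
    stop("predictions and labels must be aligned")
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  tssAt <- function(t) {
    pos <- predictions >= t
    sens <- sum(pos & labels == 1L) / sum(labels == 1L)
    spec <- sum(!pos & labels == 0L) / sum(labels == 0L)
    c(sens, spec)
  }
  if (identical(threshold, "maximize")) {
    cand <- sort(unique(predictions))
    scores <- vapply(cand, function(t) sum(tssAt(t)) - 1, 0)
    threshold <- cand[which.max(scores)]   # first index = lowest threshold
  } else if (!is.numeric(threshold)) {
    stop("threshold must be \"maximize\" or a numeric value")
  }
  ss <- tssAt(threshold)
  structure(list(sensitivity = ss[1L], specificity = ss[2L],
                 tss = ss[1L] + ss[2L] - 1,
                 threshold = as.numeric(threshold),
                 nTest = length(labels)),
            class = "tssEvaluation")
}

#' Build a TSS-gated ensemble
#'
#' Runs `nRuns` stratified splits; in each run every requested method is
#' fitted on the run's training portion (so methods within a run see
#' identical data) and evaluated on the held-out portion with the
#' maximize-TSS threshold. All members and their evaluations are retained;
#' only members with `tss > gate` participate in prediction.
#'
#' @param data an [AlignedDesignMatrix-class].
#' @param methods character vector of registry acronyms, or a list of
#'   [modelSpec()]s (their seeds are replaced by derived per-member seeds).
#' @param nRuns number of repeated splits (the reference design in the
#'   literature uses 20 runs of 10 method types, i.e. 200 members).
#' @param gate TSS gate, default 0.6.
#' @param aggregation `"mean"` (unweighted mean of member probabilities,
#'   default) or `"tss"` (TSS-weighted mean).
#' @param trainFraction training fraction per split, default 0.8.
#' @param seed master seed; per-split and per-fit seeds are derived via
#'   [seedForStage()].
#' @return An [EnsembleModel-class].
#' @export
buildEnsemble <- function(data, methods, nRuns = 20L, gate = 0.6,
                          aggregation = c("mean", "tss"),
                          trainFraction = 0.8, seed = 1L) {
  aggregation <- match.arg(aggregation)
  if (nRuns < 1L) stop("nRuns must be at least 1")
  if (is.character(methods)) methods <- lapply(methods, modelSpec)
  if (!length(methods)) stop("methods must be nonempty")
  members <- list()
  rows <- list()
  for (r in seq_len(nRuns)) {
    parts <- splitData(data, trainFraction,
                       seed = seedForStage(seed, paste0("split:", r)))
    for (spec in methods) {
      spec$seed <- seedForStage(seed, paste0("fit:", spec$method, ":", r))
      fm <- fitModel(spec, parts$train)
      ev <- evaluateTSS(predictModel(fm, parts$test),
                        parts$test@presence, "maximize")
      members[[length(members) + 1L]] <- fm
      rows[[length(rows) + 1L]] <- data.frame(
        method = spec$method, run = r,
        sensitivity = ev$sensitivity, specificity = ev$specificity,
        tss = ev$tss, threshold = ev$threshold, nTest = ev$nTest,
        stringsAsFactors = FALSE)
    }
  }
  info <- do.call(rbind, rows)
  info$included <- info$tss > gate
  if (!any(info$included))
    stop(sprintf("empty ensemble: no member exceeded the TSS gate %.2f (member TSS: %s)",
                 gate, paste(sprintf("%s/%d=%.3f", info$method, info$run,
                                     info$tss), collapse = ", ")))
  EnsembleModel(members, info, gate = gate, aggregation = aggregation)
}

#' Re-apply a (possibly different) TSS gate
#'
#' Recomputes the inclusion mask as `tss > gate` over the stored member
#' evaluations. Raising the gate can only remove members.
#'
#' @param ensemble an [EnsembleModel-class].
#' @param gate new TSS gate.
#' @return An [EnsembleModel-class] with the new gate applied. Raising the
#'   gate so that no member passes raises an error.
#' @export
applyGate <- function(ensemble, gate) {
  stopifnot(is(ensemble, "EnsembleModel"))
  info <- ensemble@memberInfo
  info$included <- info$tss > gate
  if (!any(info$included))
    stop(sprintf("empty ensemble: no member exceeded the TSS gate %.2f", gate))
  new("EnsembleModel", members = ensemble@members, memberInfo = info,
      gate = as.numeric(gate), aggregation = ensemble@aggregation,
      variables = ensemble@variables)
}

.memberWeights <- function(ensemble) {
  idx <- which(ensemble@memberInfo$included)
  w <- if (ensemble@aggregation == "tss")
    ensemble@memberInfo$tss[idx] else rep(1, length(idx))
  list(idx = idx, w = w / sum(w))
}

#' Predict with the gated committee
#'
#' Aggregates the included members' probabilities (unweighted or
#' TSS-weighted mean) for each input row.
#'
#' @param ensemble an [EnsembleModel-class] with at least one included
#'   member.
#' @param newdata feature matrix/data.frame or
#'   [AlignedDesignMatrix-class].
#' @return Numeric probability vector in \[0, 1\].
#' @export
predictEnsemble <- function(ensemble, newdata) {
  stopifnot(is(ensemble, "EnsembleModel"))
  mw <- .memberWeights(ensemble)
  if (!length(mw$idx)) stop("empty ensemble: no included members")
  preds <- vapply(mw$idx,
                  function(i) predictModel(ensemble@members[[i]], newdata),
                  numeric(nrow(.asFeatureMatrix(newdata))))
  as.numeric(if (is.null(dim(preds))) sum(preds * mw$w)
             else preds %*% mw$w)
}

#' Project the committee over a climate grid
#'
#' Aggregates the included members' per-cell predictions into one
#' suitability surface; no-data cells propagate as no-data.
#'
#' @param ensemble an [EnsembleModel-class].
#' @param grid a [ClimateGrid-class] carrying all training variables.
#' @return A [PredictionSurface-class].
#' @export
predictSurface <- function(ensemble, grid) {
  stopifnot(is(ensemble, "EnsembleModel"), is(grid, "ClimateGrid"))
  mw <- .memberWeights(ensemble)
  if (!length(mw$idx)) stop("empty ensemble: no included members")
  acc <- numeric(nCells(grid))
  for (k in seq_along(mw$idx)) {
    s <- predictModel(ensemble@members[[mw$idx[k]]], grid)
    acc <- acc + mw$w[k] * s@values
  }
  .surfaceLike(grid, acc)
}

#' Per-member evaluation report
#'
#' One row per committee member: method, run, sensitivity, specificity,
#' TSS, binarization threshold, test-set size, and whether the member
#' passed the gate.
#'
#' @param ensemble an [EnsembleModel-class].
#' @param path optional CSV output path.
#' @return The report data.frame (invisibly if `path` is given).
#' @export
ensembleReport <- function(ensemble, path = NULL) {
  stopifnot(is(ensemble, "EnsembleModel"))
  info <- ensemble@memberInfo
  if (!is.null(path)) {
    write.csv(info, path, row.names = FALSE, quote = FALSE)
    return(invisible(info))
  }
  info
}
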