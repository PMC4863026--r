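# Randomize-one-variable importance: one minus the correlation between a
# model's original predictions and its predictions after permuting one
# input column, averaged over repetitions; aggregated over ensemble members
# with the committee's own weights.

#' Permutation importance of one variable for one model
#'
#' For each repetition the variable's column is permuted (seeded), the
#' model re-predicted, and the Pearson correlation with the original
#' predictions taken; importance is the mean over repetitions of
#' `1 - correlation`. A variable the model ignores leaves predictions
#' unchanged, giving correlation 1 and importance exactly 0. Values are
#' reported as computed, not clipped: a permutation that induces negative
#' correlation yields an importance above 1.
#'
#' Degenerate cases: if the original predictions have zero variance the
#' correlation is undefined and the importance is 0 with a warning (a
#' constant model is insensitive to everything); if only the permuted
#' predictions are constant the correlation is taken as 0 (the permutation
#' destroyed all signal).
#'
#' @param model a [FittedModel-class].
#' @param data an [AlignedDesignMatrix-class] or feature matrix; by
#'   convention the full input data (train and test).
#' @param variable variable name to permute.
#' @param nReps permutation repetitions (default 5).
#' @param seed integer seed.
#' @return Numeric raw importance.
#' @export
permutationImportance <- function(model, data, variable, nReps = 5L,
                                  seed = 1L) {
  stopifnot(is(model, "FittedModel"), nReps >= 1L)
  x <- .asFeatureMatrix(data)
  if (!variable %in% colnames(x))
    stop(sprintf("variable '%s' not in data (have: %s)", variable,
                 paste(colnames(x), collapse = ", ")))
  orig <- predictModel(model, x)
  if (sd(orig) == 0) {
    warning("original predictions have zero variance; importance set to 0")
    return(0)
  }
  set.seed(seed)
  vals <- vapply(seq_len(nReps), function(rep) {
    xp <- x
    xp[, variable] <- x[sample.int(nrow(x)), variable]
    newp <- predictModel(model, xp)
    r <- if (sd(newp) == 0) 0 else cor(orig, newp)
    1 - r
  }, 0)
  mean(vals)
}

#' Ensemble-aggregated permutation importance
#'
#' Computes raw permutation importances for every (included member,
#' variable) pair and aggregates per variable with the same weights the
#' ensemble uses for prediction (equal weights for the unweighted mean,
#' TSS weights for the TSS-weighted mean) — so the reported importance is
#' weighted by the actual model contributions to the committee. Excluded
#' members contribute nothing.
#'
#' @param ensemble an [EnsembleModel-class] with at least one included
#'   member.
#' @param data an [AlignedDesignMatrix-class] or feature matrix.
#' @param nReps permutation repetitions per member/variable.
#' @param seed master seed; per-member seeds are derived via
#'   [seedForStage()].
#' @param variables variables to assess (default: all in `data`).
#' @return List of class `ImportanceTable`: `raw` (members x variables
#'   matrix over included members, rownames `method/run`), `aggregate`
#'   (named numeric per variable), `weights`, `weighting`, `nReps`,
#'   `seed`.
#' @export
ensembleImportance <- function(ensemble, data, nReps = 5L, seed = 1L,
                               variables = NULL) {
  stopifnot(is(ensemble, "EnsembleModel"))
  x <- .asFeatureMatrix(data)
  if (is.null(variables)) variables <- colnames(x)
  mw <- .memberWeights(ensemble)
  if (!length(mw$idx)) stop("empty ensemble: no included members")
  info <- ensemble@memberInfo[mw$idx, , drop = FALSE]
  raw <- matrix(NA_real_, length(mw$idx), length(variables),
                dimnames = list(paste0(info$method, "/", info$run),
                                variables))
  for (k in seq_along(mw$idx)) {
    m <- ensemble@members[[mw$idx[k]]]
    for (v in variables)
      raw[k, v] <- permutationImportance(
        m, x, v, nReps = nReps,
        seed = seedForStage(seed, paste0("imp:", info$method[k], ":",
                                         info$run[k], ":", v)))
  }
  structure(list(raw = raw,
                 aggregate = setNames(as.numeric(t(raw) %*% mw$w), variables),
                 weights = setNames(mw$w, rownames(raw)),
                 weighting = ensemble@aggregation,
                 nReps = as.integer(nReps), seed = as.integer(seed)),
            class = "ImportanceTable")
}

#' Write an importance table to CSV
#'
#' Rows are variables; columns are the included member ids plus the
#' weighted aggregate.
#'
#' @param imp an `ImportanceTable` from [ensembleImportance()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeImportance <- function(imp, path) {
  stopifnot(inherits(imp, "ImportanceTable"))
  out <- data.frame(variable = colnames(imp$raw), t(imp$raw),
                    aggregate = imp$aggregate, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
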