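# Base occurrence models behind one fit/predict contract. Native methods:
# GLM (logistic, quadratic feature expansion), GAM (mgcv), CTA (rpart),
# RF (randomForest), ANN (nnet), SRE (BIOCLIM-style quantile envelope,
# implemented here). Further acronyms (GBM, FDA, MARS, MAXENT) are open
# registry slots users can fill with registerSDMMethod().

.sdmRegistry <- new.env(parent = emptyenv())

#' Register a distribution-model method
#'
#' Adds (or replaces) an entry in the model registry. A method is a pair of
#' closures: `fit(x, y, hyper)` returning opaque learned state, and
#' `predict(fit, x, hyper)` returning occurrence probabilities in \[0, 1\]
#' for a feature matrix `x`.
#'
#' @param name registry acronym (e.g. `"GBM"`).
#' @param fit function `(x, y, hyper) -> state`; for presence-only methods
#'   `y` is all-ones.
#' @param predict function `(state, x, hyper) -> numeric in [0, 1]`.
#' @param presenceOnly logical: does the method train on presences only
#'   (like the surface range envelope)?
#' @param hyperparameters named list of default hyperparameters.
#' @return `name`, invisibly.
#' @export
registerSDMMethod <- function(name, fit, predict, presenceOnly = FALSE,
                              hyperparameters = list()) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict,
                    presenceOnly = presenceOnly,
                    hyperparameters = hyperparameters),
         envir = .sdmRegistry)
  invisible(name)
}

#' List registered model methods
#'
#' @return Character vector of registry acronyms.
#' @export
sdmMethods <- function() sort(ls(.sdmRegistry))

#' Specify a base model
#'
#' @param method a registered acronym (see [sdmMethods()]).
#' @param hyperparameters named list overriding the method's defaults.
#' @param seed integer seed for the fit.
#' @return A validated `ModelSpec` (classed list).
#' @export
modelSpec <- function(method, hyperparameters = list(), seed = 1L) {
  if (!exists(method, envir = .sdmRegistry, inherits = FALSE))
    stop(sprintf("unknown model method '%s'; registered: %s",
                 method, paste(sdmMethods(), collapse = ", ")))
  reg <- get(method, envir = .sdmRegistry)
  unknown <- setdiff(names(hyperparameters), names(reg$hyperparameters))
  if (length(unknown))
    stop(sprintf("unknown hyperparameter(s) for %s: %s (valid: %s)",
                 method, paste(unknown, collapse = ", "),
                 paste(names(reg$hyperparameters), collapse = ", ")))
  hp <- reg$hyperparameters
  hp[names(hyperparameters)] <- hyperparameters
  structure(list(method = method, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

# -- feature helpers ---------------------------------------------------------

.quadExpand <- function(x) {
  sq <- x^2
  colnames(sq) <- paste0(colnames(x), "_sq")
  cbind(x, sq)
}

.asFeatureMatrix <- function(data) {
  if (is(data, "AlignedDesignMatrix")) data@features
  else if (is.data.frame(data)) as.matrix(data)
  else as.matrix(data)
}

# -- native methods ----------------------------------------------------------

.fitGLM <- function(x, y, hyper) {
  df <- as.data.frame(.quadExpand(x))
  df$.presence <- y
  suppressWarnings(glm(.presence ~ ., data = df, family = binomial()))
}
.predictGLM <- function(fit, x, hyper) {
  p <- suppressWarnings(
    predict(fit, newdata = as.data.frame(.quadExpand(x)), type = "response"))
  as.numeric(p)
}

.fitGAM <- function(x, y, hyper) {
  df <- as.data.frame(x); df$.presence <- y
  k <- hyper$k %||% 5
  terms <- paste(sprintf("s(%s, k = %d)", colnames(x), k), collapse = " + ")
  suppressWarnings(mgcv::gam(
    stats::as.formula(paste(".presence ~", terms)),
    data = df, family = binomial(), method = "REML"))
}
.predictGAM <- function(fit, x, hyper)
  as.numeric(predict(fit, newdata = as.data.frame(x), type = "response"))

.fitCTA <- function(x, y, hyper) {
  df <- as.data.frame(x); df$.presence <- factor(y, levels = c(0, 1))
  rpart::rpart(.presence ~ ., data = df, method = "class",
               control = rpart::rpart.control(
                 xval = 0,  # no cross-validation: deterministic
                 cp = hyper$cp %||% 0.005,
                 minbucket = hyper$minbucket %||% 7))
}
.predictCTA <- function(fit, x, hyper)
  as.numeric(predict(fit, newdata = as.data.frame(x), type = "prob")[, "1"])

.fitRF <- function(x, y, hyper)
  randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                             ntree = hyper$ntree %||% 100)
.predictRF <- function(fit, x, hyper)
  as.numeric(predict(fit, newdata = x, type = "prob")[, "1"])

.fitANN <- function(x, y, hyper) {
  size <- hyper$size %||% max(2L, ceiling(sqrt(ncol(x))))
  mu <- colMeans(x); sdev <- apply(x, 2, sd); sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
  net <- nnet::nnet(xs, y, size = size, decay = hyper$decay %||% 0.01,
                    maxit = hyper$maxit %||% 200, entropy = TRUE,
                    trace = FALSE)
  list(net = net, mu = mu, sd = sdev)
}
.predictANN <- function(fit, x, hyper) {
  xs <- sweep(sweep(x, 2, fit$mu, "-"), 2, fit$sd, "/")
  as.numeric(predict(fit$net, xs, type = "raw"))
}

# BIOCLIM-style surface range envelope: per-variable presence quantile
# envelope [q, 1 - q]; a point is suitable (1) iff inside on every variable.
.fitSRE <- function(x, y, hyper) {
  q <- hyper$quantile %||% 0.025
  xp <- x[y == 1, , drop = FALSE]
  list(lower = apply(xp, 2, quantile, probs = q, type = 7, names = FALSE),
       upper = apply(xp, 2, quantile, probs = 1 - q, type = 7, names = FALSE))
}
.predictSRE <- function(fit, x, hyper) {
  inside <- rep(TRUE, nrow(x))
  for (j in seq_len(ncol(x)))
    inside <- inside & x[, j] >= fit$lower[j] & x[, j] <= fit$upper[j]
  as.numeric(inside)
}

registerSDMMethod("GLM", .fitGLM, .predictGLM,
                  hyperparameters = list())
registerSDMMethod("GAM", .fitGAM, .predictGAM,
                  hyperparameters = list(k = 5))
registerSDMMethod("CTA", .fitCTA, .predictCTA,
                  hyperparameters = list(cp = 0.005, minbucket = 7))
registerSDMMethod("RF", .fitRF, .predictRF,
                  hyperparameters = list(ntree = 100))
registerSDMMethod("ANN", .fitANN, .predictANN,
                  hyperparameters = list(size = NULL, decay = 0.01, maxit = 200))
registerSDMMethod("SRE", .fitSRE, .predictSRE, presenceOnly = TRUE,
                  hyperparameters = list(quantile = 0.025))

# -- contract ----------------------------------------------------------------

#' Fit a base model
#'
#' Fits the method named by `spec` on an aligned design. The fit is a pure
#' function of `(spec, data)`: training rows are put into a canonical order
#' before the seeded fit, so stochastic learners (RF, ANN) give identical
#' results whatever the input row order.
#'
#' @param spec a [modelSpec()].
#' @param train an [AlignedDesignMatrix-class] (or a list with elements
#'   `features` and `presence`). Discriminative methods require both
#'   classes; the presence-only SRE requires presences.
#' @return A [FittedModel-class].
#' @export
fitModel <- function(spec, train) {
  stopifnot(inherits(spec, "ModelSpec"))
  x <- .asFeatureMatrix(train)
  y <- if (is(train, "AlignedDesignMatrix")) train@presence
       else as.integer(train$presence)
  reg <- get(spec$method, envir = .sdmRegistry)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (reg$presenceOnly) {
    if (n1 == 0L)
      stop(sprintf("%s requires presence records (got %d presences)",
                   spec$method, n1))
    x <- rbind(x[y == 1L, , drop = FALSE], x[y == 0L, , drop = FALSE])
    y <- c(rep(1L, n1), rep(0L, n0))
  } else if (n1 == 0L || n0 == 0L) {
    stop(sprintf("%s requires both classes in training data (%d presences, %d absences)",
                 spec$method, n1, n0))
  }
  ord <- do.call(order, c(lapply(seq_len(ncol(x)), function(j) x[, j]),
                          list(y)))
  x <- x[ord, , drop = FALSE]; y <- y[ord]
  set.seed(spec$seed)
  state <- reg$fit(x, y, spec$hyperparameters)
  new("FittedModel", method = spec$method,
      hyperparameters = spec$hyperparameters, seed = spec$seed,
      fit = state, variables = colnames(x),
      trainingSummary = list(n = length(y), nPresence = n1, nAbsence = n0))
}

.checkColumns <- function(model, have) {
  missing <- setdiff(model@variables, have)
  if (length(missing))
    stop(sprintf("prediction input is missing training variable(s): %s",
                 paste(missing, collapse = ", ")))
}

#' Predict occurrence probabilities from a fitted model
#'
#' Row-wise map: output length equals input rows, values in \[0, 1\]
#' (binary for the surface range envelope). Columns are matched to the
#' training variables by name; extra columns are ignored. For a
#' [ClimateGrid-class] input the result is a [PredictionSurface-class]
#' with no-data cells propagated.
#'
#' @param model a [FittedModel-class].
#' @param newdata feature matrix/data.frame, [AlignedDesignMatrix-class],
#'   or [ClimateGrid-class].
#' @return Numeric probability vector, or a [PredictionSurface-class] for
#'   grid input.
#' @export
predictModel <- function(model, newdata) {
  stopifnot(is(model, "FittedModel"))
  reg <- get(model@method, envir = .sdmRegistry)
  if (is(newdata, "ClimateGrid")) {
    .checkColumns(model, variableNames(newdata))
    vals <- newdata@values[, model@variables, drop = FALSE]
    ok <- stats::complete.cases(vals)
    out <- rep(NA_real_, nrow(vals))
    if (any(ok))
      out[ok] <- pmin(1, pmax(0, reg$predict(model@fit,
                                             vals[ok, , drop = FALSE],
                                             model@hyperparameters)))
    return(.surfaceLike(newdata, out))
  }
  x <- .asFeatureMatrix(newdata)
  .checkColumns(model, colnames(x))
  x <- x[, model@variables, drop = FALSE]
  pmin(1, pmax(0, reg$predict(model@fit, x, model@hyperparameters)))
}
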