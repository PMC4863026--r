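#' climNiche: gated ensemble SDMs and climate-niche overlap
#'
#' Core containers are S4 classes: [ClimateGrid-class] holds a multi-variable
#' climate lattice, [OccurrenceSet-class] georeferenced presence/absence
#' records with population-cluster labels, [PredictionSurface-class] per-cell
#' habitat suitability, and [EnsembleModel-class] a gated committee of fitted
#' distribution models.
#'
#' @keywords internal
#' @importFrom methods new validObject is slot show setValidity
#' @importFrom stats glm binomial plogis predict quantile cor sd fft
#'   wilcox.test p.adjust rnorm runif median fivenum setNames complete.cases
#' @importFrom utils read.csv write.csv head combn
"_PACKAGE"

#' ClimateGrid: a multi-variable climate lattice
#'
#' A regular grid of cells, each carrying one value per named climate
#' variable. Cells are indexed in row-major order starting from the
#' lower-left corner: cell \eqn{k = (iy - 1) \cdot ncols + ix}, with the
#' centre of cell \eqn{(ix, iy)} at
#' \eqn{(x_0 + (ix - 0.5)\Delta,\; y_0 + (iy - 0.5)\Delta)}.
#' `NA` values mark no-data cells.
#'
#' @slot values numeric matrix, one row per cell, one named column per
#'   climate variable.
#' @slot dims integer of length 2: `c(ncols, nrows)`.
#' @slot origin numeric of length 2: coordinates of the lower-left corner.
#' @slot cellsize numeric scalar, cell edge length in map units.
#' @aliases ClimateGrid-class
#' @exportClass ClimateGrid
setClass("ClimateGrid",
  representation(values = "matrix", dims = "integer",
                 origin = "numeric", cellsize = "numeric"))

setValidity("ClimateGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 2L || any(object@dims < 1L))
    msg <- c(msg, "dims must be two positive integers (ncols, nrows)")
  else if (nrow(object@values) != prod(object@dims))
    msg <- c(msg, sprintf("values has %d rows but dims imply %d cells",
                          nrow(object@values), prod(object@dims)))
  vn <- colnames(object@values)
  if (is.null(vn) || anyDuplicated(vn) || any(!nzchar(vn)))
    msg <- c(msg, "values must have unique, non-empty column names")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must have length 2")
  if (length(object@cellsize) != 1L || object@cellsize <= 0)
    msg <- c(msg, "cellsize must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a ClimateGrid
#'
#' @param values numeric matrix (cells x variables) with variable names as
#'   column names; cells in row-major order from the lower-left corner.
#' @param ncols,nrows grid dimensions in cells.
#' @param origin lower-left corner coordinates, default `c(0, 0)`.
#' @param cellsize cell edge length, default 1.
#' @return A [ClimateGrid-class] object.
#' @export
#' @examples
#' g <- ClimateGrid(matrix(rnorm(32), 16, 2,
#'                  dimnames = list(NULL, c("dd5", "MAP"))), 4, 4)
#' gridDim(g)
ClimateGrid <- function(values, ncols, nrows, origin = c(0, 0), cellsize = 1) {
  new("ClimateGrid", values = as.matrix(values),
      dims = as.integer(c(ncols, nrows)),
      origin = as.numeric(origin), cellsize = as.numeric(cellsize))
}

#' OccurrenceSet: presence/absence point records
#'
#' Point records with coordinates, a presence flag (1 = presence,
#' 0 = absence) and a population-cluster label (e.g. `"NC"`, `"SC"`;
#' absences conventionally carry `"none"`).
#'
#' @slot records data.frame with columns `x`, `y`, `presence`, `cluster`.
#' @aliases OccurrenceSet-class
#' @exportClass OccurrenceSet
setClass("OccurrenceSet", representation(records = "data.frame"))

setValidity("OccurrenceSet", function(object) {
  r <- object@records
  need <- c("x", "y", "presence", "cluster")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r) && !all(r$presence %in% c(0L, 1L)))
    return("presence must be 0 or 1")
  TRUE
})

#' Construct an OccurrenceSet
#'
#' @param x,y numeric coordinates.
#' @param presence integer vector of 0/1 flags.
#' @param cluster character cluster labels (recycled); use `"none"` for
#'   records not assigned to a population cluster (typically absences).
#' @return An [OccurrenceSet-class] object.
#' @export
OccurrenceSet <- function(x, y, presence, cluster = "none") {
  new("OccurrenceSet", records = data.frame(
    x = as.numeric(x), y = as.numeric(y),
    presence = as.integer(presence),
    cluster = as.character(rep_len(cluster, length(x))),
    stringsAsFactors = FALSE))
}

#' PredictionSurface: per-cell habitat suitability
#'
#' A single layer on the same lattice geometry as a [ClimateGrid-class],
#' holding suitability values in \[0, 1\] (`NA` = no-data).
#'
#' @slot values numeric vector, one value per cell.
#' @slot dims,origin,cellsize grid geometry, as in [ClimateGrid-class].
#' @aliases PredictionSurface-class
#' @exportClass PredictionSurface
setClass("PredictionSurface",
  representation(values = "numeric", dims = "integer",
                 origin = "numeric", cellsize = "numeric"))

setValidity("PredictionSurface", function(object) {
  if (length(object@values) != prod(object@dims))
    return(sprintf("surface has %d values but dims imply %d cells",
                   length(object@values), prod(object@dims)))
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("surface values must lie in [0, 1]")
  TRUE
})

#' NormalizedSurface: an occurrence-probability surface summing to one
#'
#' A [PredictionSurface-class] whose non-missing cell weights are
#' nonnegative and sum to 1; this is the form entering the Schoener's D and
#' Hellinger I overlap statistics.
#'
#' @aliases NormalizedSurface-class
#' @exportClass NormalizedSurface
setClass("NormalizedSurface", contains = "PredictionSurface")

setValidity("NormalizedSurface", function(object) {
  v <- object@values[!is.na(object@values)]
  if (!length(v)) return("normalized surface has no valid cells")
  if (min(v) < 0) return("normalized surface has negative weights")
  if (abs(sum(v) - 1) > 1e-9)
    return(sprintf("weights sum to %.12f, not 1", sum(v)))
  TRUE
})

#' AlignedDesignMatrix: occurrence records aligned to grid cells
#'
#' The model-ready design: one row per retained occurrence record, one
#' column per climate variable, plus the presence label and the provenance
#' mapping record -> cell. Records falling off-grid or on no-data cells are
#' dropped and counted.
#'
#' @slot features numeric matrix (records x variables), no missing values.
#' @slot presence integer 0/1 labels, one per row.
#' @slot cell integer cell index of each row.
#' @slot recordId integer row index of each retained record in the source
#'   [OccurrenceSet-class].
#' @slot nDropped integer: records excluded (off-grid or no-data).
#' @aliases AlignedDesignMatrix-class
#' @exportClass AlignedDesignMatrix
setClass("AlignedDesignMatrix",
  representation(features = "matrix", presence = "integer",
                 cell = "integer", recordId = "integer",
                 nDropped = "integer"))

setValidity("AlignedDesignMatrix", function(object) {
  n <- nrow(object@features)
  if (length(object@presence) != n || length(object@cell) != n ||
      length(object@recordId) != n)
    return("features, presence, cell and recordId must agree in length")
  if (anyNA(object@features))
    return("features must not contain missing values")
  if (n && !all(object@presence %in% c(0L, 1L)))
    return("presence must be 0 or 1")
  TRUE
})

#' FittedModel: one fitted base distribution model
#'
#' A single member of the model committee: the method name (registry
#' acronym), its hyperparameters and seed, the opaque learned state, and a
#' training summary (row count and class balance).
#'
#' @slot method registry acronym, e.g. `"GLM"`, `"SRE"`, `"RF"`.
#' @slot hyperparameters named list.
#' @slot seed integer seed the fit was performed under.
#' @slot fit opaque learned state (method-specific).
#' @slot variables training variable names, in training order.
#' @slot trainingSummary list with at least `n`, `nPresence`, `nAbsence`.
#' @aliases FittedModel-class
#' @exportClass FittedModel
setClass("FittedModel",
  representation(method = "character", hyperparameters = "list",
                 seed = "integer", fit = "ANY", variables = "character",
                 trainingSummary = "list"))

#' EnsembleModel: a TSS-gated committee of fitted models
#'
#' All fitted members are retained together with their evaluation
#' (sensitivity, specificity, TSS on a held-out split); only members whose
#' TSS exceeds the gate participate in prediction. Aggregation is the
#' unweighted mean of member probabilities by default, or a TSS-weighted
#' mean.
#'
#' @slot members list of [FittedModel-class] objects.
#' @slot memberInfo data.frame, one row per member: `method`, `run`,
#'   `sensitivity`, `specificity`, `tss`, `threshold`, `nTest`, `included`.
#' @slot gate numeric TSS gate; members with `tss > gate` are included.
#' @slot aggregation `"mean"` or `"tss"` (TSS-weighted mean).
#' @slot variables climate variable names the members were trained on.
#' @aliases EnsembleModel-class
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(members = "list", memberInfo = "data.frame",
                 gate = "numeric", aggregation = "character",
                 variables = "character"))

setValidity("EnsembleModel", function(object) {
  if (nrow(object@memberInfo) != length(object@members))
    return("memberInfo must have one row per member")
  need <- c("method", "run", "sensitivity", "specificity", "tss",
            "threshold", "nTest", "included")
  if (!all(need %in% names(object@memberInfo)))
    return(sprintf("memberInfo must have columns %s",
                   paste(need, collapse = ", ")))
  if (!object@aggregation %in% c("mean", "tss"))
    return("aggregation must be 'mean' or 'tss'")
  info <- object@memberInfo
  if (nrow(info) && any(info$included & !(info$tss > object@gate)))
    return("included members must all have tss > gate")
  TRUE
})

#' Construct an EnsembleModel from fitted members and their evaluations
#'
#' Normally produced by [buildEnsemble()]; the constructor is exported so
#' committees can be assembled from externally fitted members. The
#' inclusion mask is recomputed from `tss > gate`.
#'
#' @param members list of [FittedModel-class] objects.
#' @param memberInfo data.frame with columns `method`, `run`, `sensitivity`,
#'   `specificity`, `tss`, `threshold`, `nTest` (and optionally `included`,
#'   which is recomputed).
#' @param gate TSS gate (default 0.6).
#' @param aggregation `"mean"` (default) or `"tss"`.
#' @return An [EnsembleModel-class].
#' @export
EnsembleModel <- function(members, memberInfo, gate = 0.6,
                          aggregation = c("mean", "tss")) {
  aggregation <- match.arg(aggregation)
  memberInfo$included <- memberInfo$tss > gate
  vars <- if (length(members)) members[[1]]@variables else character()
  new("EnsembleModel", members = members, memberInfo = memberInfo,
      gate = as.numeric(gate), aggregation = aggregation, variables = vars)
}
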