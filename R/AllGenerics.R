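# Generics for the core containers. Accessor implementations live in
# accessors.R; show methods in show-methods.R.

#' @rdname ClimateGrid
#' @param object,x a climNiche S4 object
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname ClimateGrid
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname ClimateGrid
#' @export
setGeneric("gridCellsize", function(x) standardGeneric("gridCellsize"))

#' @rdname ClimateGrid
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname ClimateGrid
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname ClimateGrid
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname ClimateGrid
#' @export
setGeneric("cellCoordinates", function(x) standardGeneric("cellCoordinates"))

#' Map point coordinates to cell indices
#'
#' Cells are half-open intervals: a point belongs to cell
#' `floor((coord - origin) / cellsize) + 1` on each axis, so a point lying
#' exactly on a shared edge belongs to the upper/right cell. Points outside
#' the grid map to `NA`.
#'
#' @param x a [ClimateGrid-class] or [PredictionSurface-class].
#' @param px,py numeric point coordinates.
#' @return Integer cell indices (row-major from the lower-left), `NA` for
#'   points off the grid.
#' @export
setGeneric("cellFromXY", function(x, px, py) standardGeneric("cellFromXY"))

#' @rdname PredictionSurface
#' @export
setGeneric("surfaceValues", function(x) standardGeneric("surfaceValues"))

#' @rdname OccurrenceSet
#' @export
setGeneric("nPresence", function(x) standardGeneric("nPresence"))

#' @rdname OccurrenceSet
#' @export
setGeneric("nAbsence", function(x) standardGeneric("nAbsence"))

#' @rdname OccurrenceSet
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname OccurrenceSet
#' @export
setGeneric("presences", function(x) standardGeneric("presences"))

#' @rdname OccurrenceSet
#' @export
setGeneric("absences", function(x) standardGeneric("absences"))

#' @rdname AlignedDesignMatrix
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname AlignedDesignMatrix
#' @export
setGeneric("presenceLabels", function(x) standardGeneric("presenceLabels"))

#' @rdname AlignedDesignMatrix
#' @export
setGeneric("droppedRecords", function(x) standardGeneric("droppedRecords"))

#' @rdname EnsembleModel
#' @export
setGeneric("memberInfo", function(x) standardGeneric("memberInfo"))

#' @rdname EnsembleModel
#' @export
setGeneric("gateThreshold", function(x) standardGeneric("gateThreshold"))

#' @rdname EnsembleModel
#' @export
setGeneric("aggregationRule", function(x) standardGeneric("aggregationRule"))

#' @rdname EnsembleModel
#' @export
setGeneric("includedMembers", function(x) standardGeneric("includedMembers"))
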