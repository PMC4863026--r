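#' @describeIn ClimateGrid grid dimensions `c(ncols, nrows)`.
#' @export
setMethod("gridDim", "ClimateGrid", function(x) x@dims)

#' @describeIn ClimateGrid lower-left corner coordinates.
#' @export
setMethod("gridOrigin", "ClimateGrid", function(x) x@origin)

#' @describeIn ClimateGrid cell edge length.
#' @export
setMethod("gridCellsize", "ClimateGrid", function(x) x@cellsize)

#' @describeIn ClimateGrid number of cells.
#' @export
setMethod("nCells", "ClimateGrid", function(x) nrow(x@values))

#' @describeIn ClimateGrid climate variable names.
#' @export
setMethod("variableNames", "ClimateGrid", function(x) colnames(x@values))

#' @describeIn ClimateGrid cells x variables value matrix.
#' @export
setMethod("gridValues", "ClimateGrid", function(x) x@values)

#' @describeIn ClimateGrid two-column matrix of cell-centre coordinates,
#'   row-major from the lower-left corner.
#' @export
setMethod("cellCoordinates", "ClimateGrid", function(x) {
  nc <- x@dims[1L]; nr <- x@dims[2L]
  ix <- rep(seq_len(nc), times = nr)
  iy <- rep(seq_len(nr), each = nc)
  cbind(x = x@origin[1L] + (ix - 0.5) * x@cellsize,
        y = x@origin[2L] + (iy - 0.5) * x@cellsize)
})

.cellFromXY <- function(dims, origin, cellsize, px, py) {
  ix <- floor((px - origin[1L]) / cellsize) + 1
  iy <- floor((py - origin[2L]) / cellsize) + 1
  ok <- ix >= 1 & ix <= dims[1L] & iy >= 1 & iy <= dims[2L]
  out <- rep(NA_integer_, length(px))
  out[ok] <- as.integer((iy[ok] - 1) * dims[1L] + ix[ok])
  out
}

#' @rdname cellFromXY
#' @export
setMethod("cellFromXY", "ClimateGrid", function(x, px, py)
  .cellFromXY(x@dims, x@origin, x@cellsize, px, py))

#' @rdname cellFromXY
#' @export
setMethod("cellFromXY", "PredictionSurface", function(x, px, py)
  .cellFromXY(x@dims, x@origin, x@cellsize, px, py))

#' @describeIn PredictionSurface per-cell values (NA = no-data).
#' @param x a [PredictionSurface-class]
#' @export
setMethod("surfaceValues", "PredictionSurface", function(x) x@values)

#' @describeIn PredictionSurface geometry accessors shared with ClimateGrid.
#' @export
setMethod("gridDim", "PredictionSurface", function(x) x@dims)

#' @export
#' @describeIn PredictionSurface lower-left corner.
setMethod("gridOrigin", "PredictionSurface", function(x) x@origin)

#' @export
#' @describeIn PredictionSurface cell edge length.
setMethod("gridCellsize", "PredictionSurface", function(x) x@cellsize)

#' @export
#' @describeIn PredictionSurface number of cells.
setMethod("nCells", "PredictionSurface", function(x) length(x@values))

#' Coerce an OccurrenceSet to a data.frame
#'
#' @param x an [OccurrenceSet-class].
#' @param ... ignored.
#' @return data.frame with columns `x`, `y`, `presence`, `cluster`.
#' @method as.data.frame OccurrenceSet
#' @export
as.data.frame.OccurrenceSet <- function(x, ...) x@records

setMethod("as.data.frame", "OccurrenceSet", as.data.frame.OccurrenceSet)

#' @describeIn OccurrenceSet number of presence records.
#' @param x an [OccurrenceSet-class]
#' @export
setMethod("nPresence", "OccurrenceSet", function(x) sum(x@records$presence == 1L))

#' @describeIn OccurrenceSet number of absence records.
#' @export
setMethod("nAbsence", "OccurrenceSet", function(x) sum(x@records$presence == 0L))

#' @describeIn OccurrenceSet cluster labels present among the records.
#' @export
setMethod("clusterLabels", "OccurrenceSet",
          function(x) sort(unique(x@records$cluster)))

#' @describeIn OccurrenceSet subset to presence records.
#' @export
setMethod("presences", "OccurrenceSet", function(x)
  new("OccurrenceSet", records = x@records[x@records$presence == 1L, , drop = FALSE]))

#' @describeIn OccurrenceSet subset to absence records.
#' @export
setMethod("absences", "OccurrenceSet", function(x)
  new("OccurrenceSet", records = x@records[x@records$presence == 0L, , drop = FALSE]))

#' Subset an OccurrenceSet by record index
#' @param x an [OccurrenceSet-class]
#' @param i integer or logical index
#' @param j,drop,... ignored
#' @export
setMethod("[", "OccurrenceSet", function(x, i, j, ..., drop = FALSE)
  new("OccurrenceSet", records = x@records[i, , drop = FALSE]))

#' Combine OccurrenceSets
#' @param x,... [OccurrenceSet-class] objects.
#' @export
setMethod("rbind2", signature("OccurrenceSet", "OccurrenceSet"),
          function(x, y) new("OccurrenceSet", records = rbind(x@records, y@records)))

#' Concatenate occurrence sets
#'
#' @param ... [OccurrenceSet-class] objects.
#' @return One [OccurrenceSet-class] with all records in order.
#' @export
bindOccurrences <- function(...) {
  sets <- list(...)
  new("OccurrenceSet",
      records = do.call(rbind, lapply(sets, function(s) s@records)))
}

#' @describeIn AlignedDesignMatrix feature matrix (records x variables).
#' @param x an [AlignedDesignMatrix-class]
#' @export
setMethod("features", "AlignedDesignMatrix", function(x) x@features)

#' @describeIn AlignedDesignMatrix integer 0/1 presence labels.
#' @export
setMethod("presenceLabels", "AlignedDesignMatrix", function(x) x@presence)

#' @describeIn AlignedDesignMatrix number of records dropped during
#'   alignment (off-grid or no-data).
#' @export
setMethod("droppedRecords", "AlignedDesignMatrix", function(x) x@nDropped)

#' @describeIn AlignedDesignMatrix variable names.
#' @export
setMethod("variableNames", "AlignedDesignMatrix", function(x) colnames(x@features))

#' Subset an AlignedDesignMatrix by row
#' @param x an [AlignedDesignMatrix-class]
#' @param i integer or logical row index
#' @param j,drop,... ignored
#' @export
setMethod("[", "AlignedDesignMatrix", function(x, i, j, ..., drop = FALSE)
  new("AlignedDesignMatrix",
      features = x@features[i, , drop = FALSE],
      presence = x@presence[i], cell = x@cell[i],
      recordId = x@recordId[i], nDropped = 0L))

#' @describeIn EnsembleModel per-member evaluation table.
#' @param x an [EnsembleModel-class]
#' @export
setMethod("memberInfo", "EnsembleModel", function(x) x@memberInfo)

#' @describeIn EnsembleModel the TSS gate.
#' @export
setMethod("gateThreshold", "EnsembleModel", function(x) x@gate)

#' @describeIn EnsembleModel aggregation rule, `"mean"` or `"tss"`.
#' @export
setMethod("aggregationRule", "EnsembleModel", function(x) x@aggregation)

#' @describeIn EnsembleModel indices of members passing the gate.
#' @export
setMethod("includedMembers", "EnsembleModel",
          function(x) which(x@memberInfo$included))

#' @describeIn EnsembleModel variable names the committee was trained on.
#' @export
setMethod("variableNames", "EnsembleModel", function(x) x@variables)
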