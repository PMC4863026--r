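setMethod("show", "ClimateGrid", function(object) {
  d <- object@dims
  cat(sprintf("ClimateGrid: %d x %d cells (%d), %d variable(s)\n",
              d[1L], d[2L], prod(d), ncol(object@values)))
  cat("  variables:", paste(colnames(object@values), collapse = ", "), "\n")
  nNA <- sum(!stats::complete.cases(object@values))
  if (nNA) cat(sprintf("  no-data cells: %d\n", nNA))
  cat(sprintf("  origin (%g, %g), cellsize %g\n",
              object@origin[1L], object@origin[2L], object@cellsize))
})

setMethod("show", "OccurrenceSet", function(object) {
  r <- object@records
  cat(sprintf("OccurrenceSet: %d records (%d presences, %d absences)\n",
              nrow(r), sum(r$presence == 1L), sum(r$presence == 0L)))
  tab <- table(r$cluster)
  cat("  clusters:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "PredictionSurface", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("%s: %d x %d cells", class(object),
              object@dims[1L], object@dims[2L]))
  if (length(v))
    cat(sprintf(", values in [%.4g, %.4g]", min(v), max(v)))
  cat(sprintf(", %d no-data\n", sum(is.na(object@values))))
})

setMethod("show", "AlignedDesignMatrix", function(object) {
  cat(sprintf(
    "AlignedDesignMatrix: %d records x %d variables (%d pres / %d abs), %d dropped\n",
    nrow(object@features), ncol(object@features),
    sum(object@presence == 1L), sum(object@presence == 0L), object@nDropped))
})

setMethod("show", "FittedModel", function(object) {
  ts <- object@trainingSummary
  cat(sprintf("FittedModel <%s> on %d rows (%d pres / %d abs), seed %d\n",
              object@method, ts$n %||% NA_integer_,
              ts$nPresence %||% NA_integer_, ts$nAbsence %||% NA_integer_,
              object@seed))
})

setMethod("show", "EnsembleModel", function(object) {
  info <- object@memberInfo
  cat(sprintf("EnsembleModel: %d members, %d pass TSS gate > %.2f (%s aggregation)\n",
              nrow(info), sum(info$included), object@gate,
              if (object@aggregation == "mean") "unweighted mean"
              else "TSS-weighted mean"))
  if (nrow(info)) {
    agg <- tapply(info$tss, info$method, median)
    cat("  median member TSS by method:",
        paste(sprintf("%s %.3f", names(agg), agg), collapse = ", "), "\n")
  }
})
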