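`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically fans one master seed out to independent per-stage seeds
#' by hashing the stage name, so pipeline stages can be re-run in isolation
#' while the whole study stays reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. `"split:3"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' seedForStage(42, "simulate")
#' seedForStage(42, "fit:GLM:1")
seedForStage <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483629
  as.integer(((abs(as.numeric(master)) %% 2147483647) * 7919 + h) %% 2147483647)
}

# new surface sharing a grid/surface's geometry
.surfaceLike <- function(geom, values, class = "PredictionSurface") {
  new(class, values = as.numeric(values), dims = geom@dims,
      origin = geom@origin, cellsize = geom@cellsize)
}

.sameGeometry <- function(a, b) {
  identical(a@dims, b@dims) &&
    isTRUE(all.equal(a@origin, b@origin)) &&
    isTRUE(all.equal(a@cellsize, b@cellsize))
}

# full-precision number formatting for lossless text round-trips
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
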