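# Reading/writing climate grids and occurrence tables; aligning points to
# cells. The plain-text grid format is canonical and lossless; TIFF export
# uses one 32-bit float page per band plus a JSON sidecar carrying
# georeferencing, band names and per-band scaling (TIFF stores [0,1]).

#' Write a climate grid
#'
#' `format = "textgrid"` writes a self-describing plain-text file: a header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `variables`)
#' followed by one whitespace-separated row per cell (row-major from the
#' lower-left corner), full double precision, `NA` for no-data. The
#' write/read round trip is lossless.
#'
#' `format = "tiff"` writes a multi-page 32-bit float TIFF (one page per
#' band, top row first) with a `<path>.json` sidecar holding geometry,
#' band names and per-band min/max used to scale values into \[0, 1\];
#' the round trip is value-identical to single-float precision.
#'
#' @param grid a [ClimateGrid-class].
#' @param path output file path.
#' @param format `"textgrid"` (default) or `"tiff"`.
#' @return `path`, invisibly.
#' @seealso [readGrid()]
#' @export
writeGrid <- function(grid, path, format = c("textgrid", "tiff")) {
  stopifnot(is(grid, "ClimateGrid"))
  format <- match.arg(format)
  if (format == "textgrid") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste("ncols", grid@dims[1L]),
      paste("nrows", grid@dims[2L]),
      paste("xllcorner", .fmtNum(grid@origin[1L])),
      paste("yllcorner", .fmtNum(grid@origin[2L])),
      paste("cellsize", .fmtNum(grid@cellsize)),
      paste("variables", paste(variableNames(grid), collapse = " "))), con)
    body <- apply(grid@values, 1L, function(r) paste(.fmtNum(r), collapse = " "))
    writeLines(body, con)
  } else {
    nc <- grid@dims[1L]; nr <- grid@dims[2L]
    pages <- list(); lo <- hi <- numeric(ncol(grid@values))
    for (j in seq_len(ncol(grid@values))) {
      v <- grid@values[, j]
      lo[j] <- min(v, na.rm = TRUE); hi[j] <- max(v, na.rm = TRUE)
      scl <- if (hi[j] > lo[j]) (v - lo[j]) / (hi[j] - lo[j]) else v * 0
      scl[is.na(scl)] <- 0   # no-data mask lives in the sidecar
      m <- matrix(scl, nr, nc, byrow = TRUE)   # row-major from lower-left
      pages[[j]] <- m[nr:1, , drop = FALSE]    # TIFF rows run top-down
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    sidecar <- list(ncols = nc, nrows = nr,
                    xllcorner = grid@origin[1L], yllcorner = grid@origin[2L],
                    cellsize = grid@cellsize,
                    variables = variableNames(grid),
                    band_min = lo, band_max = hi,
                    nodata_cells = which(!stats::complete.cases(grid@values)))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a climate grid
#'
#' @param path file path as written by [writeGrid()].
#' @param format `"textgrid"` (default) or `"tiff"` (expects the
#'   `<path>.json` sidecar next to the file).
#' @return A [ClimateGrid-class].
#' @export
readGrid <- function(path, format = c("textgrid", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read grid: no such file: ", path)
  if (format == "textgrid") {
    lines <- readLines(path)
    hdr <- strsplit(lines[1:6], "\\s+")
    key <- vapply(hdr, `[`, "", 1L)
    need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "variables")
    if (!identical(key, need))
      stop("malformed textgrid header in ", path, " (expected keys: ",
           paste(need, collapse = ", "), ")")
    nc <- as.integer(hdr[[1]][2]); nr <- as.integer(hdr[[2]][2])
    vars <- hdr[[6]][-1L]
    body <- lines[-(1:6)]
    if (length(body) != nc * nr)
      stop(sprintf("textgrid %s has %d data rows but header implies %d cells",
                   path, length(body), nc * nr))
    raw <- unlist(strsplit(body, "\\s+"))
    raw[raw == "NA"] <- NA_character_
    vals <- matrix(as.numeric(raw), ncol = length(vars), byrow = TRUE,
                   dimnames = list(NULL, vars))
    ClimateGrid(vals, nc, nr,
                origin = c(as.numeric(hdr[[3]][2]), as.numeric(hdr[[4]][2])),
                cellsize = as.numeric(hdr[[5]][2]))
  } else {
    sidecarPath <- paste0(path, ".json")
    if (!file.exists(sidecarPath))
      stop("missing sidecar ", sidecarPath, " for tiff grid")
    sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != length(sc$variables))
      stop(sprintf("tiff %s has %d bands but sidecar names %d variables",
                   path, length(pages), length(sc$variables)))
    nc <- sc$ncols; nr <- sc$nrows
    vals <- matrix(0, nc * nr, length(pages),
                   dimnames = list(NULL, sc$variables))
    for (j in seq_along(pages)) {
      m <- pages[[j]][nr:1, , drop = FALSE]        # back to bottom-up rows
      v <- as.numeric(t(m))                        # row-major cell order
      vals[, j] <- v * (sc$band_max[j] - sc$band_min[j]) + sc$band_min[j]
    }
    if (length(sc$nodata_cells)) vals[sc$nodata_cells, ] <- NA_real_
    ClimateGrid(vals, nc, nr,
                origin = c(sc$xllcorner, sc$yllcorner), cellsize = sc$cellsize)
  }
}

#' Write occurrence records to CSV
#'
#' Comma-separated with header, columns `x,y,presence,cluster`, UTF-8.
#'
#' @param occ an [OccurrenceSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  stopifnot(is(occ, "OccurrenceSet"))
  write.csv(occ@records, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read occurrence records from CSV
#'
#' @param path CSV with columns `x,y,presence` and optionally `cluster`.
#' @return An [OccurrenceSet-class].
#' @export
readOccurrences <- function(path) {
  if (!file.exists(path)) stop("cannot read occurrences: no such file: ", path)
  d <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("x", "y", "presence")
  if (!all(need %in% names(d)))
    stop("occurrence CSV must have columns x, y, presence; found: ",
         paste(names(d), collapse = ", "))
  OccurrenceSet(d$x, d$y, d$presence,
                if ("cluster" %in% names(d)) d$cluster else "none")
}

#' Align occurrence records to grid cells and extract climate features
#'
#' Maps each record to the cell containing it (half-open cells, floor
#' convention: a point on a shared edge belongs to the upper/right cell).
#' Records outside the grid or on no-data cells are dropped; the count is
#' recorded in the result and reported via a message. Retained records keep
#' their input order, so the operation is idempotent and order-preserving.
#'
#' @param grid a [ClimateGrid-class].
#' @param occ an [OccurrenceSet-class] in the grid's coordinate system.
#' @return An [AlignedDesignMatrix-class].
#' @export
extractFeatures <- function(grid, occ) {
  stopifnot(is(grid, "ClimateGrid"), is(occ, "OccurrenceSet"))
  r <- occ@records
  cell <- cellFromXY(grid, r$x, r$y)
  keep <- !is.na(cell)
  feat <- matrix(NA_real_, nrow(r), ncol(grid@values),
                 dimnames = list(NULL, variableNames(grid)))
  feat[keep, ] <- grid@values[cell[keep], , drop = FALSE]
  keep <- keep & stats::complete.cases(feat)
  nDropped <- sum(!keep)
  if (!any(keep)) stop("no occurrences on grid")
  if (nDropped)
    message(sprintf("extractFeatures: dropped %d record(s) (off-grid or no-data)",
                    nDropped))
  new("AlignedDesignMatrix",
      features = feat[keep, , drop = FALSE],
      presence = as.integer(r$presence[keep]),
      cell = cell[keep],
      recordId = which(keep),
      nDropped = as.integer(nDropped))
}
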