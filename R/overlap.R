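# Niche overlap between predicted occupancy surfaces: Schoener's D and the
# Hellinger-derived I statistic, computed over normalized surfaces on a
# shared cell set.

#' Normalize a suitability surface to occurrence probabilities
#'
#' Divides every valid (non-missing) cell value by the sum over valid
#' cells, yielding the per-cell occurrence probabilities \eqn{p_i} entering
#' the overlap statistics. Already-normalized surfaces pass through
#' unchanged.
#'
#' @param surface a [PredictionSurface-class] with nonnegative values and
#'   at least one positive cell.
#' @return A [NormalizedSurface-class].
#' @export
normalizeSurface <- function(surface) {
  stopifnot(is(surface, "PredictionSurface"))
  v <- surface@values
  ok <- !is.na(v)
  tot <- sum(v[ok])
  if (tot <= 0) stop("cannot normalize null surface (all valid cells are zero)")
  .surfaceLike(surface, ifelse(ok, v / tot, NA_real_),
               class = "NormalizedSurface")
}

.checkShared <- function(px, py) {
  vx <- if (is(px, "PredictionSurface")) px@values else as.numeric(px)
  vy <- if (is(py, "PredictionSurface")) py@values else as.numeric(py)
  if (length(vx) != length(vy) ||
      !identical(which(is.na(vx)), which(is.na(vy))))
    stop(sprintf("surfaces must share one cell set (%d vs %d valid cells)",
                 sum(!is.na(vx)), sum(!is.na(vy))))
  list(x = vx[!is.na(vx)], y = vy[!is.na(vy)])
}

#' Schoener's D niche overlap
#'
#' \deqn{D(p_x, p_y) = 1 - \tfrac12 \sum_i |p_{x,i} - p_{y,i}|}
#' over two normalized occurrence-probability surfaces on a shared cell
#' set. D is symmetric and lies in \[0, 1\]: 0 means no overlap (disjoint
#' supports), 1 complete overlap (identical surfaces).
#'
#' @param px,py [NormalizedSurface-class] objects (or bare normalized
#'   weight vectors) on the same cell set.
#' @return Numeric D in \[0, 1\].
#' @export
#' @examples
#' schoenerD(c(.5, .5, 0), c(0, .5, .5))  # 0.5
schoenerD <- function(px, py) {
  p <- .checkShared(px, py)
  1 - 0.5 * sum(abs(p$x - p$y))
}

#' Hellinger-based I niche overlap
#'
#' The `"hellinger"` variant is the modified Hellinger statistic
#' \deqn{I = 1 - \tfrac12 \sum_i (\sqrt{p_{x,i}} - \sqrt{p_{y,i}})^2,}
#' i.e. one minus half the squared Hellinger distance. The `"printed"`
#' variant omits the square roots,
#' \deqn{I = 1 - \tfrac12 \sum_i (p_{x,i} - p_{y,i})^2,}
#' a form that also appears typeset in the applied literature; it is kept
#' for fidelity to such reports. Both are symmetric and equal 1 iff the
#' surfaces are identical; the Hellinger variant is 0 iff supports are
#' disjoint.
#'
#' @param px,py [NormalizedSurface-class] objects (or bare normalized
#'   weight vectors) on the same cell set.
#' @param variant `"hellinger"` (default) or `"printed"`.
#' @return Numeric I.
#' @export
#' @examples
#' hellingerI(c(.5, .5), c(1, 0))               # ~0.7071
#' hellingerI(c(.5, .5), c(1, 0), "printed")    # 0.75
hellingerI <- function(px, py, variant = c("hellinger", "printed")) {
  variant <- match.arg(variant)
  p <- .checkShared(px, py)
  if (variant == "hellinger") 1 - 0.5 * sum((sqrt(p$x) - sqrt(p$y))^2)
  else 1 - 0.5 * sum((p$x - p$y)^2)
}

#' Pairwise niche overlap among prediction surfaces
#'
#' Normalizes each surface over the cells valid in both members of a pair
#' (pairwise-complete) and reports D and I for every unordered pair. Both
#' statistics are symmetric, so each pair appears once.
#'
#' @param surfaces named list of [PredictionSurface-class] objects on one
#'   shared grid geometry.
#' @param variant I variant passed to [hellingerI()].
#' @return data.frame with columns `surfaceX`, `surfaceY`, `d`, `i`,
#'   `iVariant`, `nCells`.
#' @export
pairwiseOverlap <- function(surfaces, variant = c("hellinger", "printed")) {
  variant <- match.arg(variant)
  if (length(surfaces) < 2L) stop("need at least 2 surfaces")
  nm <- names(surfaces)
  if (is.null(nm) || any(!nzchar(nm))) stop("surfaces must be named")
  geomOK <- vapply(surfaces[-1L], .sameGeometry, TRUE, surfaces[[1L]])
  if (!all(geomOK))
    stop("all surfaces must share one grid geometry")
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- surfaces[[pairs[1L, k]]]; b <- surfaces[[pairs[2L, k]]]
    ok <- !is.na(a@values) & !is.na(b@values)
    va <- a@values; va[!ok] <- NA_real_
    vb <- b@values; vb[!ok] <- NA_real_
    pa <- normalizeSurface(.surfaceLike(a, va))
    pb <- normalizeSurface(.surfaceLike(b, vb))
    data.frame(surfaceX = pairs[1L, k], surfaceY = pairs[2L, k],
               d = schoenerD(pa, pb), i = hellingerI(pa, pb, variant),
               iVariant = variant, nCells = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
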