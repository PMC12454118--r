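#' @include grid-geometry.R
NULL

#' Resample a layer onto a target grid
#'
#' Interpolates `x` at the cell centres of `target`. `"bilinear"` is the
#' appropriate choice for continuous surfaces (yield, richness, harvested
#' area); `"nearest"` copies the nearest source cell and is idempotent on
#' matching grids.
#'
#' Masked-cell policy under bilinear: a target cell is masked only when
#' every source cell of its 2 x 2 interpolation stencil is masked (or the
#' centre falls outside the source extent); otherwise masked neighbours
#' are dropped and the remaining weights renormalised, which avoids
#' eroding the coastlines of sparse crop maps. The output is a convex
#' combination of unmasked stencil values, so it never overshoots the
#' stencil's minimum or maximum. Target centres beyond the outermost
#' source cell centres but still inside the source extent use
#' constant (edge) extrapolation.
#'
#' Bilinear resampling is not mass-conserving: grid totals (e.g. summed
#' harvested area) may change. With `options(BiodivPressure.verbose =
#' TRUE)` the pre/post totals and their relative change are reported; no
#' renormalisation is applied.
#'
#' @param x a [Layer-class].
#' @param target the [GridSpec-class] to resample onto.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A [Layer-class] on `target`; the unit tag is unchanged.
#' @examples
#' sp <- gridSpec(4, 4, cellSize = 10, originLon = 0, originLat = 40)
#' gr <- layer(sp, outer(1:4, 1:4, "+"), units = "t")
#' fine <- gridSpec(8, 8, cellSize = 5, originLon = 0, originLat = 40)
#' alignToGrid(gr, fine)
#' @export
alignToGrid <- function(x, target, method = c("bilinear", "nearest")) {
  stopifnot(is(x, "Layer"), is(target, "GridSpec"))
  method <- match.arg(method)
  src <- x@spec
  if (sameGrid(src, target))
    return(layer(target, x@values, units = x@units))

  sLonMax <- src@originLon + src@nCols * src@cellSize
  sLatMin <- src@originLat - src@nRows * src@cellSize
  tLonMax <- target@originLon + target@nCols * target@cellSize
  tLatMin <- target@originLat - target@nRows * target@cellSize
  if (target@originLon >= sLonMax || tLonMax <= src@originLon ||
      tLatMin >= src@originLat || target@originLat <= sLatMin)
    stop("grids do not overlap: cannot resample", call. = FALSE)

  lons <- centerLons(target)
  lats <- centerLats(target)
  # fractional source indices of the target centres (1 = first centre)
  fx <- (lons - src@originLon) / src@cellSize + 0.5
  fy <- (src@originLat - lats) / src@cellSize + 0.5
  outCol <- lons < src@originLon | lons > sLonMax
  outRow <- lats > src@originLat | lats < sLatMin
  S <- x@values

  if (method == "nearest") {
    j <- pmin(pmax(floor(fx + 0.5), 1L), src@nCols)
    i <- pmin(pmax(floor(fy + 0.5), 1L), src@nRows)
    out <- S[i, j, drop = FALSE]
  } else {
    # clamp to the centre hull: edge extrapolation is constant
    fxc <- pmin(pmax(fx, 1), src@nCols)
    fyc <- pmin(pmax(fy, 1), src@nRows)
    j0 <- pmin(pmax(floor(fxc), 1L), max(src@nCols - 1L, 1L))
    i0 <- pmin(pmax(floor(fyc), 1L), max(src@nRows - 1L, 1L))
    j1 <- pmin(j0 + 1L, src@nCols)
    i1 <- pmin(i0 + 1L, src@nRows)
    wx <- fxc - j0
    wy <- fyc - i0
    num <- matrix(0, target@nRows, target@nCols)
    den <- matrix(0, target@nRows, target@nCols)
    addCorner <- function(ii, jj, W) {
      V <- S[ii, jj, drop = FALSE]
      ok <- !is.na(V)
      V[!ok] <- 0
      num <<- num + W * V
      den <<- den + W * ok
    }
    addCorner(i0, j0, (1 - wy) %o% (1 - wx))
    addCorner(i0, j1, (1 - wy) %o% wx)
    addCorner(i1, j0, wy %o% (1 - wx))
    addCorner(i1, j1, wy %o% wx)
    out <- num / den
    out[den < 1e-12] <- NA_real_
  }
  if (any(outRow)) out[outRow, ] <- NA_real_
  if (any(outCol)) out[, outCol] <- NA_real_

  if (isTRUE(getOption("BiodivPressure.verbose", FALSE))) {
    pre <- sum(S, na.rm = TRUE)
    post <- sum(out, na.rm = TRUE)
    message(sprintf(
      "alignToGrid[%s]: total %.6g -> %.6g (relative change %+.3g)",
      method, pre, post, if (pre != 0) (post - pre) / pre else NA_real_
    ))
  }
  layer(target, out, units = x@units)
}
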