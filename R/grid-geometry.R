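#' @include AllClasses.R
NULL

# Two specs describe the same grid (exact-ish float comparison).
sameGrid <- function(a, b, tol = 1e-9) {
  a@nRows == b@nRows && a@nCols == b@nCols &&
    abs(a@cellSize - b@cellSize) < tol &&
    abs(a@originLon - b@originLon) < tol &&
    abs(a@originLat - b@originLat) < tol
}

stopIfGridMismatch <- function(a, b, what = "layers") {
  if (!sameGrid(a, b))
    stop("grid mismatch: ", what, " are not on the same grid; ",
         "align them with alignToGrid() first", call. = FALSE)
  invisible(TRUE)
}

# Cell-centre coordinate vectors of a grid (row 1 = northmost).
centerLats <- function(spec)
  spec@originLat - (seq_len(spec@nRows) - 0.5) * spec@cellSize
centerLons <- function(spec)
  spec@originLon + (seq_len(spec@nCols) - 0.5) * spec@cellSize

#' Spherical cell areas of an equal-angle grid
#'
#' Per-cell area in hectares from the spherical band formula
#' \deqn{A = R^2 \, \Delta\lambda \, (\sin\varphi_{top} - \sin\varphi_{bot})}
#' on the authalic sphere (R = 6,371,007.2 m). The area is constant within
#' a latitude row, symmetric about the equator, and strictly decreasing
#' with absolute latitude; summed over a full global grid the areas close
#' to the sphere surface \eqn{4\pi R^2} exactly (telescoping sum).
#'
#' @param spec a [GridSpec-class].
#' @return A [Layer-class] with units `"ha"`.
#' @examples
#' ## a 5-arcmin cell at the equator is about 8.59e3 ha
#' sp <- gridSpec(1, 1, cellSize = 5 / 60, originLon = 0, originLat = 5 / 60)
#' layerValues(cellArea(sp))[1, 1]
#' @export
cellArea <- function(spec) {
  stopifnot(is(spec, "GridSpec"))
  validObject(spec)
  deg2rad <- pi / 180
  latTop <- spec@originLat - (seq_len(spec@nRows) - 1L) * spec@cellSize
  latBot <- latTop - spec@cellSize
  bandM2 <- EARTH_RADIUS_M^2 * (spec@cellSize * deg2rad) *
    (sin(latTop * deg2rad) - sin(latBot * deg2rad))
  ha <- bandM2 / 1e4
  layer(spec, matrix(ha, spec@nRows, spec@nCols), units = "ha")
}
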