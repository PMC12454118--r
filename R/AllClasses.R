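#' @import methods
NULL

# Authalic Earth radius (m); sphere of the same surface area as the WGS84
# ellipsoid. Sub-0.3% cell-area error versus the ellipsoid at 5 arcmin.
EARTH_RADIUS_M <- 6371007.2

#' GridSpec: geometry of an equal-angle raster grid
#'
#' Describes a latitude--longitude lattice with square angular cells.
#' Registration is corner-based: `originLon`/`originLat` give the
#' north-west corner of the grid, row 1 is the northernmost row, and cell
#' values are located at cell centres for interpolation purposes.
#'
#' @slot nRows,nCols number of rows / columns (positive integers).
#' @slot cellSize angular cell size in decimal degrees (> 0).
#' @slot originLon,originLat longitude / latitude of the north-west corner,
#'   in decimal degrees.
#'
#' @seealso [gridSpec()], [cellArea()], [Layer-class]
#' @export
setClass("GridSpec",
  representation(
    nRows = "integer", nCols = "integer", cellSize = "numeric",
    originLon = "numeric", originLat = "numeric"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single positive integer")
  if (length(object@nCols) != 1L || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single positive integer")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  eps <- 1e-6
  if (length(msg) == 0L) {
    if (object@nRows * object@cellSize > 180 + eps)
      msg <- c(msg, "grid spans more than 180 degrees of latitude")
    if (object@nCols * object@cellSize > 360 + eps)
      msg <- c(msg, "grid spans more than 360 degrees of longitude")
    if (object@originLat > 90 + eps || object@originLat - object@nRows *
        object@cellSize < -90 - eps)
      msg <- c(msg, "grid extends beyond the poles")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSize angular cell size in degrees. The default, 5 arcmin
#'   (0.0833333 degrees), matches the resolution of circa-2000 global crop
#'   grids.
#' @param originLon,originLat north-west corner in degrees.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(24, 48, cellSize = 7.5)
#' @export
gridSpec <- function(nRows, nCols, cellSize = 5 / 60,
                     originLon = -180, originLat = 90) {
  new("GridSpec",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    cellSize = as.numeric(cellSize),
    originLon = as.numeric(originLon), originLat = as.numeric(originLat)
  )
}

#' Layer: a gridded field with units and a missing-data mask
#'
#' A 2-D field on a [GridSpec-class] grid. Values are stored as a
#' `nRows x nCols` numeric matrix with row 1 northmost; `NA` encodes a
#' masked (missing-data) cell. Every unmasked value is finite. The unit
#' tag is free text (e.g. `"ha"`, `"t"`, `"species"`, `"species.ha"`,
#' `"species.ha t-1"`) and every operation either preserves it or
#' transforms it explicitly.
#'
#' @slot spec the grid geometry.
#' @slot values numeric matrix, `NA` = masked.
#' @slot units unit tag.
#' @seealso [layer()], [layerValues()], [alignToGrid()]
#' @export
setClass("Layer",
  representation(spec = "GridSpec", values = "matrix", units = "character")
)

setValidity("Layer", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (d[1] != object@spec@nRows || d[2] != object@spec@nCols)
    msg <- c(msg, sprintf(
      "values are %d x %d but the grid is %d x %d",
      d[1], d[2], object@spec@nRows, object@spec@nCols
    ))
  v <- object@values
  if (any(!is.finite(v) & !is.na(v)))
    msg <- c(msg, "unmasked values must be finite (use NA for masked cells)")
  if (length(object@units) != 1L)
    msg <- c(msg, "units must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Layer
#'
#' @param spec a [GridSpec-class].
#' @param values numeric matrix (`nRows x nCols`, `NA` = masked) or a single
#'   number recycled to the whole grid.
#' @param units unit tag.
#' @return A [Layer-class].
#' @examples
#' sp <- gridSpec(4, 8, cellSize = 10)
#' layer(sp, 1, units = "species")
#' @export
layer <- function(spec, values, units = "") {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec@nRows, spec@nCols)
  storage.mode(values) <- "double"
  new("Layer", spec = spec, values = values, units = units)
}

#' CropData: one crop's harvested-area and yield layers plus water content
#'
#' @slot cropId crop identifier.
#' @slot harvestedArea [Layer-class] of harvested hectares per cell;
#'   non-negative and bounded by the spherical cell area.
#' @slot yield [Layer-class] of fresh-weight yield in t/ha; non-negative.
#' @slot waterPct water content in percent, in `[0, 100)`; used for
#'   dry-weight conversion, fresh tonnes times `(1 - waterPct/100)`.
#' @seealso [cropData()], [computeProduction()]
#' @export
setClass("CropData",
  representation(
    cropId = "character", harvestedArea = "Layer",
    yield = "Layer", waterPct = "numeric"
  )
)

setValidity("CropData", function(object) {
  msg <- character()
  ha <- object@harvestedArea
  yl <- object@yield
  if (!sameGrid(ha@spec, yl@spec))
    msg <- c(msg, "harvestedArea and yield must share one grid")
  if (any(ha@values < 0, na.rm = TRUE))
    msg <- c(msg, "harvested area must be non-negative")
  if (any(yl@values < 0, na.rm = TRUE))
    msg <- c(msg, "yield must be non-negative")
  if (length(object@waterPct) != 1L || is.na(object@waterPct) ||
      object@waterPct < 0 || object@waterPct >= 100)
    msg <- c(msg, "waterPct must lie in [0, 100)")
  if (length(msg) == 0L) {
    ca <- cellArea(ha@spec)@values
    if (any(ha@values > ca * (1 + 1e-9), na.rm = TRUE))
      msg <- c(msg, "harvested area exceeds the cell area in some cells")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CropData object
#'
#' @param cropId crop identifier string.
#' @param harvestedArea,yield aligned [Layer-class] objects (ha per cell;
#'   t/ha fresh weight).
#' @param waterPct water content in percent, `[0, 100)`.
#' @return A [CropData-class].
#' @export
cropData <- function(cropId, harvestedArea, yield, waterPct) {
  new("CropData",
    cropId = as.character(cropId), harvestedArea = harvestedArea,
    yield = yield, waterPct = as.numeric(waterPct)
  )
}

#' CountryZones: fractional-coverage mapping from countries to grid cells
#'
#' Each row of `zones` states that a fraction `coverage` of grid cell
#' `cell` (a linear index into the layer matrix, column-major as in R)
#' belongs to `country`. Coverages per cell sum to at most 1, so a cell
#' split between countries is counted fractionally in zonal statistics.
#'
#' @slot spec the grid the cell indices refer to.
#' @slot zones data.frame with columns `country`, `cell`, `coverage`.
#' @seealso [countryZones()], [countrySum()], [countryBP()]
#' @export
setClass("CountryZones",
  representation(spec = "GridSpec", zones = "data.frame")
)

setValidity("CountryZones", function(object) {
  z <- object@zones
  msg <- character()
  need <- c("country", "cell", "coverage")
  if (!all(need %in% names(z)))
    return("zones must have columns country, cell, coverage")
  ncell <- object@spec@nRows * object@spec@nCols
  if (nrow(z)) {
    if (any(z$cell < 1 | z$cell > ncell))
      msg <- c(msg, "zone cell index out of grid")
    if (any(z$coverage <= 0 | z$coverage > 1 + 1e-9))
      msg <- c(msg, "coverage fractions must lie in (0, 1]")
    tot <- tapply(z$coverage, z$cell, sum)
    if (any(tot > 1 + 1e-6))
      msg <- c(msg, "coverage fractions of a cell sum to more than 1")
  } else {
    msg <- c(msg, "zones must contain at least one cell entry")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CountryZones object
#'
#' @param spec the [GridSpec-class] the cell indices refer to.
#' @param zones data.frame with columns `country` (id string), `cell`
#'   (linear cell index), `coverage` (fraction in `(0, 1]`).
#' @return A [CountryZones-class].
#' @export
countryZones <- function(spec, zones) {
  zones$country <- as.character(zones$country)
  zones$cell <- as.integer(zones$cell)
  zones$coverage <- as.numeric(zones$coverage)
  new("CountryZones", spec = spec, zones = zones)
}

#' TradeTable: bilateral crop trade flows
#'
#' One record per (origin, destination, crop): `tonnes` of the crop moving
#' from `origin` to `destination` per year. Origins never equal
#' destinations and tonnes are non-negative.
#'
#' @slot flows data.frame with columns `origin`, `destination`, `crop`,
#'   `tonnes`.
#' @seealso [tradeTable()], [bpCons()], [splitSupply()]
#' @export
setClass("TradeTable", representation(flows = "data.frame"))

setValidity("TradeTable", function(object) {
  f <- object@flows
  need <- c("origin", "destination", "crop", "tonnes")
  if (!all(need %in% names(f)))
    return("flows must have columns origin, destination, crop, tonnes")
  msg <- character()
  if (nrow(f)) {
    if (any(f$tonnes < 0)) msg <- c(msg, "trade tonnes must be non-negative")
    if (any(f$origin == f$destination))
      msg <- c(msg, "origin must differ from destination")
    key <- paste(f$origin, f$destination, f$crop, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "at most one record per (origin, destination, crop)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TradeTable
#'
#' @param flows data.frame with columns `origin`, `destination`, `crop`,
#'   `tonnes` (may have zero rows for an autarkic world).
#' @return A [TradeTable-class].
#' @export
tradeTable <- function(flows = data.frame(
                         origin = character(), destination = character(),
                         crop = character(), tonnes = numeric()
                       )) {
  flows$origin <- as.character(flows$origin)
  flows$destination <- as.character(flows$destination)
  flows$crop <- as.character(flows$crop)
  flows$tonnes <- as.numeric(flows$tonnes)
  new("TradeTable", flows = flows)
}

#' ConsumptionPressure: the trade decomposition of consumption pressure
#'
#' Result of [bpCons()]: the pressure embedded in a focal country's
#' consumption of one crop, split into the domestic term (domestic supply
#' times the focal country's per-tonne BP) and one import term per origin
#' (import tonnes times the origin's country-level BP). Import tonnes from
#' origins for which no BP is available are never silently dropped; they
#' accumulate in `unattributedImportTonnes`.
#'
#' @slot focal,crop identifiers.
#' @slot domesticSupply domestic supply in tonnes (production minus
#'   exports, clamped at zero).
#' @slot domesticTerm species.ha of the domestic component.
#' @slot importTerms named numeric, species.ha per import origin.
#' @slot bpCons total pressure, `domesticTerm + sum(importTerms)`.
#' @slot unattributedImportTonnes import tonnes lacking an origin BP.
#' @export
setClass("ConsumptionPressure",
  representation(
    focal = "character", crop = "character",
    domesticSupply = "numeric", domesticTerm = "numeric",
    importTerms = "numeric", bpCons = "numeric",
    unattributedImportTonnes = "numeric"
  )
)

setValidity("ConsumptionPressure", function(object) {
  msg <- character()
  terms <- c(object@domesticTerm, object@importTerms)
  if (any(terms < 0)) msg <- c(msg, "all pressure terms must be non-negative")
  tot <- object@domesticTerm + sum(object@importTerms)
  if (abs(tot - object@bpCons) > 1e-9 * max(1, abs(tot)))
    msg <- c(msg, "bpCons must equal domesticTerm + sum(importTerms)")
  if (length(msg)) msg else TRUE
})

#' WorldConfig: parameters of the synthetic world generator
#'
#' @slot grid analysis grid (default a coarse 24 x 48 global equal-angle
#'   grid, 7.5-degree cells).
#' @slot nCountries number of contiguous countries to grow (>= 2).
#' @slot nCrops number of crops (>= 1).
#' @slot richnessRange integer range of the spatially autocorrelated
#'   species-richness surface.
#' @slot cropSparsity fraction of cells with positive harvested area.
#' @slot yieldRange fresh-weight yield range, t/ha.
#' @slot waterRange water-content range in percent.
#' @slot tradeDensity fraction of feasible (origin, destination, crop)
#'   triples that carry a flow.
#' @slot seed root random seed; fanned out to named substreams.
#' @seealso [worldConfig()], [generateWorld()]
#' @export
setClass("WorldConfig",
  representation(
    grid = "GridSpec", nCountries = "integer", nCrops = "integer",
    richnessRange = "numeric", cropSparsity = "numeric",
    yieldRange = "numeric", waterRange = "numeric",
    tradeDensity = "numeric", seed = "integer"
  )
)

setValidity("WorldConfig", function(object) {
  msg <- character()
  if (object@nCountries < 2L) msg <- c(msg, "nCountries must be >= 2")
  if (object@nCrops < 1L) msg <- c(msg, "nCrops must be >= 1")
  okRange <- function(r) length(r) == 2L && all(is.finite(r)) &&
    r[1] <= r[2] && r[1] >= 0
  if (!okRange(object@richnessRange))
    msg <- c(msg, "richnessRange must be an ordered non-negative pair")
  if (!okRange(object@yieldRange))
    msg <- c(msg, "yieldRange must be an ordered non-negative pair")
  if (!okRange(object@waterRange) || object@waterRange[2] >= 100)
    msg <- c(msg, "waterRange must be an ordered pair in [0, 100)")
  if (object@cropSparsity < 0 || object@cropSparsity > 1)
    msg <- c(msg, "cropSparsity must lie in [0, 1]")
  if (object@tradeDensity < 0 || object@tradeDensity > 1)
    msg <- c(msg, "tradeDensity must lie in [0, 1]")
  nc <- object@grid@nRows * object@grid@nCols
  if (object@nCountries > nc)
    msg <- c(msg, "nCountries exceeds the number of grid cells")
  if (length(msg)) msg else TRUE
})
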