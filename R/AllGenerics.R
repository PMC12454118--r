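#' @include AllClasses.R
NULL

#' Accessors for grid and layer objects
#'
#' `layerValues` returns the value matrix (`NA` = masked), `layerUnits` the
#' unit tag, `gridOf` the [GridSpec-class] carried by an object, `nRows`,
#' `nCols` and `cellSize` the grid dimensions, `zonesTable` the zone
#' data.frame of a [CountryZones-class], and `tradeFlows` the flow
#' data.frame of a [TradeTable-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))
#' @rdname accessors
#' @export
setGeneric("layerUnits", function(x) standardGeneric("layerUnits"))
#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))
#' @rdname accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("zonesTable", function(x) standardGeneric("zonesTable"))
#' @rdname accessors
#' @export
setGeneric("tradeFlows", function(x) standardGeneric("tradeFlows"))

#' @rdname accessors
#' @export
setMethod("layerValues", "Layer", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("layerUnits", "Layer", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("gridOf", "Layer", function(x) x@spec)
#' @rdname accessors
#' @export
setMethod("gridOf", "CountryZones", function(x) x@spec)
#' @rdname accessors
#' @export
setMethod("gridOf", "CropData", function(x) x@harvestedArea@spec)
#' @rdname accessors
#' @export
setMethod("nRows", "GridSpec", function(x) x@nRows)
#' @rdname accessors
#' @export
setMethod("nCols", "GridSpec", function(x) x@nCols)
#' @rdname accessors
#' @export
setMethod("cellSize", "GridSpec", function(x) x@cellSize)
#' @rdname accessors
#' @export
setMethod("zonesTable", "CountryZones", function(x) x@zones)
#' @rdname accessors
#' @export
setMethod("tradeFlows", "TradeTable", function(x) x@flows)

#' Accessors for ConsumptionPressure results
#'
#' @param x a [ConsumptionPressure-class].
#' @return `bpConsTotal` the total pressure (species.ha), `domesticTerm`
#'   the domestic component, `importTerms` the named per-origin components,
#'   `unattributedImports` the import tonnes that could not be attributed
#'   to an origin BP.
#' @name consumption-accessors
NULL

#' @rdname consumption-accessors
#' @export
setGeneric("bpConsTotal", function(x) standardGeneric("bpConsTotal"))
#' @rdname consumption-accessors
#' @export
setGeneric("domesticTerm", function(x) standardGeneric("domesticTerm"))
#' @rdname consumption-accessors
#' @export
setGeneric("importTerms", function(x) standardGeneric("importTerms"))
#' @rdname consumption-accessors
#' @export
setGeneric("unattributedImports", function(x)
  standardGeneric("unattributedImports"))

#' @rdname consumption-accessors
#' @export
setMethod("bpConsTotal", "ConsumptionPressure", function(x) x@bpCons)
#' @rdname consumption-accessors
#' @export
setMethod("domesticTerm", "ConsumptionPressure", function(x) x@domesticTerm)
#' @rdname consumption-accessors
#' @export
setMethod("importTerms", "ConsumptionPressure", function(x) x@importTerms)
#' @rdname consumption-accessors
#' @export
setMethod("unattributedImports", "ConsumptionPressure",
  function(x) x@unattributedImportTonnes)

#' @describeIn consumption-accessors one-row data.frame summary of the
#'   decomposition.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "ConsumptionPressure",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
      focal = x@focal, crop = x@crop,
      domestic_supply_t = x@domesticSupply,
      domestic_term = x@domesticTerm,
      import_term = sum(x@importTerms),
      bp_cons = x@bpCons,
      unattributed_import_t = x@unattributedImportTonnes,
      stringsAsFactors = FALSE
    )
  })

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %g deg, NW corner (%g, %g)\n",
    object@nRows, object@nCols, object@cellSize,
    object@originLon, object@originLat
  ))
})

setMethod("show", "Layer", function(object) {
  v <- object@values
  nm <- sum(is.na(v))
  rng <- if (all(is.na(v))) c(NA_real_, NA_real_) else range(v, na.rm = TRUE)
  cat(sprintf(
    "Layer [%s]: %d x %d, range [%g, %g], %d masked cell%s\n",
    object@units, nrow(v), ncol(v), rng[1], rng[2], nm,
    if (nm == 1L) "" else "s"
  ))
})

setMethod("show", "CropData", function(object) {
  cat(sprintf(
    "CropData '%s': water %.1f%%\n  harvested area: ", object@cropId,
    object@waterPct
  ))
  show(object@harvestedArea)
  cat("  yield: ")
  show(object@yield)
})

setMethod("show", "CountryZones", function(object) {
  z <- object@zones
  cat(sprintf(
    "CountryZones: %d countr%s over %d cell entries on a %d x %d grid\n",
    length(unique(z$country)),
    if (length(unique(z$country)) == 1L) "y" else "ies",
    nrow(z), object@spec@nRows, object@spec@nCols
  ))
})

setMethod("show", "TradeTable", function(object) {
  f <- object@flows
  cat(sprintf(
    "TradeTable: %d flow%s, %d crop%s, %.6g t total\n",
    nrow(f), if (nrow(f) == 1L) "" else "s",
    length(unique(f$crop)), if (length(unique(f$crop)) == 1L) "" else "s",
    sum(f$tonnes)
  ))
})

setMethod("show", "ConsumptionPressure", function(object) {
  cat(sprintf(
    "ConsumptionPressure %s / %s: BP_cons %.6g species.ha (domestic %.6g, imports %.6g over %d origin%s)\n",
    object@focal, object@crop, object@bpCons, object@domesticTerm,
    sum(object@importTerms), length(object@importTerms),
    if (length(object@importTerms) == 1L) "" else "s"
  ))
  if (object@unattributedImportTonnes > 0)
    cat(sprintf(
      "  unattributed imports: %.6g t\n", object@unattributedImportTonnes
    ))
})

setMethod("show", "WorldConfig", function(object) {
  cat(sprintf(
    "WorldConfig: %d x %d grid, %d countries, %d crops, seed %d\n",
    object@grid@nRows, object@grid@nCols, object@nCountries,
    object@nCrops, object@seed
  ))
})
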