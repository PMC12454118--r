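#' @include grid-geometry.R
NULL

#' Per-cell crop production
#'
#' Production is the product of yield (t/ha, fresh weight) and harvested
#' area (ha) in each cell. With `dry = TRUE` (the default, and the basis
#' used throughout the country aggregation) fresh tonnes are converted to
#' dry weight by multiplying by `1 - waterPct/100`.
#'
#' @param crop a [CropData-class].
#' @param dry convert to dry-weight tonnes?
#' @return A [Layer-class] with units `"t"`; masked where either input is
#'   masked.
#' @examples
#' sp <- gridSpec(1, 1, cellSize = 1, originLon = 0, originLat = 1)
#' cr <- cropData("tomato", layer(sp, 3, "ha"), layer(sp, 2, "t ha-1"), 90)
#' layerValues(computeProduction(cr, dry = FALSE)) # 6 t fresh
#' layerValues(computeProduction(cr))              # 0.6 t dry
#' @export
computeProduction <- function(crop, dry = TRUE) {
  stopifnot(is(crop, "CropData"))
  stopIfGridMismatch(crop@harvestedArea@spec, crop@yield@spec,
                     "harvested area and yield")
  p <- crop@yield@values * crop@harvestedArea@values
  if (dry) p <- p * (1 - crop@waterPct / 100)
  layer(crop@harvestedArea@spec, p, units = "t")
}

#' Affected species range (ASR) per cell
#'
#' The per-cell product of harvested area (ha) and species richness
#' (species count): the extent of species ranges overlapped by the crop's
#' cultivated area.
#'
#' @param crop a [CropData-class].
#' @param richness a [Layer-class] of vertebrate species richness
#'   (non-negative; integer counts before resampling, real-valued surfaces
#'   after bilinear alignment are accepted).
#' @return A [Layer-class] with units `"species.ha"`; masked where either
#'   input is masked; non-negative wherever defined.
#' @export
computeASR <- function(crop, richness) {
  stopifnot(is(crop, "CropData"), is(richness, "Layer"))
  stopIfGridMismatch(crop@harvestedArea@spec, richness@spec,
                     "harvested area and richness")
  if (any(richness@values < 0, na.rm = TRUE))
    stop("richness must be non-negative", call. = FALSE)
  layer(crop@harvestedArea@spec,
        crop@harvestedArea@values * richness@values,
        units = "species.ha")
}

#' Per-cell biodiversity pressure (BP)
#'
#' The per-tonne pressure intensity: ASR divided by production,
#' `BP = (HA x SR) / P`, in species.ha per tonne. Cells where production
#' is below `tol` (or masked) are masked rather than made infinite:
#' floating-point noise from resampling must not create astronomically
#' large BP cells.
#'
#' @param crop a [CropData-class].
#' @param richness richness [Layer-class].
#' @param production production [Layer-class] from [computeProduction()],
#'   on the weight basis configured for the analysis; computed on the fly
#'   (dry basis) when omitted.
#' @param tol zero-production tolerance in tonnes (default `1e-9`).
#' @return A [Layer-class] with units `"species.ha t-1"`.
#' @examples
#' sp <- gridSpec(1, 1, cellSize = 1, originLon = 0, originLat = 1)
#' cr <- cropData("kale", layer(sp, 2, "ha"), layer(sp, 2, "t ha-1"), 0)
#' sr <- layer(sp, 5, "species")
#' layerValues(computeBP(cr, sr)) # (2*5)/(2*2) = 2.5
#' @export
computeBP <- function(crop, richness,
                      production = computeProduction(crop),
                      tol = 1e-9) {
  asr <- computeASR(crop, richness)
  stopIfGridMismatch(asr@spec, production@spec, "ASR and production")
  p <- production@values
  bp <- asr@values / p
  bp[is.na(p) | p < tol] <- NA_real_
  layer(asr@spec, bp, units = "species.ha t-1")
}

#' Read a water-content table
#'
#' CSV with columns `crop_id` and `water_pct` (percent water content of
#' the fresh commodity). Used for dry-weight conversion of production and
#' of trade tonnes.
#'
#' @param path CSV file path.
#' @param required crop ids that must be present; an informative error
#'   lists any that are missing.
#' @return data.frame with columns `crop_id`, `water_pct`.
#' @export
readWaterTable <- function(path, required = NULL) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("crop_id", "water_pct") %in% names(w)))
    stop("water-content table needs columns crop_id, water_pct",
         call. = FALSE)
  if (any(w$water_pct < 0 | w$water_pct >= 100))
    stop("water_pct must lie in [0, 100)", call. = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, w$crop_id)
    if (length(miss))
      stop("water content missing for crop(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  w[, c("crop_id", "water_pct")]
}

# Dry-weight factor for a crop id, from a water table data.frame.
dryFactor <- function(cropIds, waterTable) {
  i <- match(cropIds, waterTable$crop_id)
  if (anyNA(i))
    stop("water content missing for crop(s): ",
         paste(unique(cropIds[is.na(i)]), collapse = ", "), call. = FALSE)
  1 - waterTable$water_pct[i] / 100
}
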