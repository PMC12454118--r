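#' @include grid-geometry.R
NULL

#' Fractional-coverage zonal sum
#'
#' Per-country total of a layer: for country i,
#' `sum_l coverage[i, l] * value[l]`. Masked cells contribute 0.
#'
#' @param x a [Layer-class].
#' @param zones a [CountryZones-class] on the same grid.
#' @return Named numeric vector of totals, sorted by country id.
#' @examples
#' sp <- gridSpec(1, 2, cellSize = 1, originLon = 0, originLat = 1)
#' ly <- layer(sp, matrix(c(3, 4), 1), "t")
#' cz <- countryZones(sp, data.frame(country = "AAA", cell = 1:2, coverage = 1))
#' countrySum(ly, cz) # 7
#' @export
countrySum <- function(x, zones) {
  stopifnot(is(x, "Layer"), is(zones, "CountryZones"))
  stopIfGridMismatch(x@spec, zones@spec, "layer and zones")
  z <- zones@zones
  v <- x@values[z$cell]
  v[is.na(v)] <- 0
  res <- tapply(z$coverage * v, z$country, sum)
  out <- as.numeric(res)
  names(out) <- names(res)
  out[order(names(out))]
}

#' Production-weighted country mean of per-cell BP
#'
#' The country-level per-tonne pressure: the mean of cell BP over the
#' cells of a country, weighted by (coverage-fraction scaled) production,
#' `BP_i = sum_l f_il P_l BP_l / sum_l f_il P_l`. Cells masked in `bp`
#' (zero production) are excluded from numerator and denominator alike.
#' A country with no production weight gets `NA` -- "no production" is
#' not "zero pressure".
#'
#' The weighting encodes the trade-attribution assumption that exports
#' are sourced proportionally to where production is largest within a
#' country.
#'
#' @param bp per-cell BP [Layer-class] (from [computeBP()]).
#' @param production production [Layer-class] on the same weight basis
#'   used to form `bp`.
#' @param zones a [CountryZones-class].
#' @return Named numeric vector of country BP values (species.ha per t),
#'   sorted by country id; `NA` for countries without production.
#' @export
countryBP <- function(bp, production, zones) {
  stopifnot(is(bp, "Layer"), is(production, "Layer"),
            is(zones, "CountryZones"))
  stopIfGridMismatch(bp@spec, production@spec, "BP and production")
  stopIfGridMismatch(bp@spec, zones@spec, "BP and zones")
  z <- zones@zones
  b <- bp@values[z$cell]
  p <- production@values[z$cell]
  w <- z$coverage * p
  w[is.na(w) | is.na(b)] <- 0
  b[is.na(b)] <- 0
  num <- tapply(w * b, z$country, sum)
  den <- tapply(w, z$country, sum)
  out <- as.numeric(num) / as.numeric(den)
  out[as.numeric(den) <= 0] <- NA_real_
  names(out) <- names(num)
  out[order(names(out))]
}

#' National production pressure
#'
#' The pressure of a country's production of a crop: the country's
#' production-weighted mean BP times its total production. By the algebra
#' of the cell-level definitions this equals the country-summed ASR when
#' the same coverage weights are used (`sum P * (ASR/P) = sum ASR`).
#'
#' @param bpMean country BP values (from [countryBP()]).
#' @param productionTotal country production totals (from [countrySum()]),
#'   matched by name when both are named.
#' @return Numeric vector of BP_prod in species.ha; `NA` where `bpMean`
#'   is missing.
#' @export
bpProd <- function(bpMean, productionTotal) {
  if (!is.null(names(bpMean)) && !is.null(names(productionTotal)))
    productionTotal <- productionTotal[names(bpMean)]
  bpMean * productionTotal
}

#' Per-country, per-crop pressure metrics table
#'
#' Runs the cell-level metrics and the zonal aggregation for a set of
#' crops: total production (tonnes, on the chosen weight basis), total
#' ASR (species.ha), the production-weighted mean BP (species.ha per
#' tonne), and BP_prod (= bp_mean x production_total).
#'
#' @param crops list of [CropData-class] objects.
#' @param richness richness [Layer-class] on the same grid.
#' @param zones a [CountryZones-class].
#' @param dry use dry-weight production (default) or fresh.
#' @param tol zero-production tolerance in tonnes.
#' @param exclude country ids to drop from the output (e.g. territories
#'   outside the study scope).
#' @return data.frame with one row per (country, crop): columns `country`,
#'   `crop`, `production_total`, `asr_total`, `bp_mean`, `bp_prod`.
#'   Countries without production of a crop carry `NA` in `bp_mean` and
#'   `bp_prod`, never 0.
#' @export
countryCropMetrics <- function(crops, richness, zones, dry = TRUE,
                               tol = 1e-9, exclude = character()) {
  stopifnot(length(crops) >= 1L)
  res <- lapply(crops, function(cr) {
    p <- computeProduction(cr, dry = dry)
    asr <- computeASR(cr, richness)
    bp <- computeBP(cr, richness, production = p, tol = tol)
    pTot <- countrySum(p, zones)
    aTot <- countrySum(asr, zones)
    bMean <- countryBP(bp, p, zones)
    data.frame(
      country = names(pTot), crop = cr@cropId,
      production_total = as.numeric(pTot),
      asr_total = as.numeric(aTot),
      bp_mean = as.numeric(bMean[names(pTot)]),
      bp_prod = as.numeric(bpProd(bMean, pTot)[names(pTot)]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[!(out$country %in% exclude), , drop = FALSE]
  out <- out[order(out$crop, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dense descending ranks of a metrics table
#'
#' Ranks entities by a metric column: rank 1 is the largest value, tied
#' values share a dense rank, and rows are ordered by rank with ties
#' broken by identifier in lexicographic order.
#'
#' @param table data.frame of metrics.
#' @param by name of the metric column to rank by.
#' @param idCol name of the identifier column used for tie-break ordering.
#' @return `table` sorted by rank (then id), with a leading `rank` column.
#' @examples
#' rankEntities(data.frame(id = c("a", "b", "c"), v = c(5, 7, 5)), "v", "id")
#' @export
rankEntities <- function(table, by, idCol = names(table)[1]) {
  if (!by %in% names(table))
    stop("unknown metric: ", by, call. = FALSE)
  if (!idCol %in% names(table))
    stop("unknown id column: ", idCol, call. = FALSE)
  v <- table[[by]]
  lev <- sort(unique(v[!is.na(v)]), decreasing = TRUE)
  rk <- match(v, lev)
  out <- cbind(rank = rk, table)
  ord <- order(rk, as.character(table[[idCol]]), na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
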