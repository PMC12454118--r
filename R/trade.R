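#' @include AllClasses.R
NULL

#' Domestic supply: production minus exports
#'
#' The tonnage of a crop grown and retained in a country. When exports
#' exceed production (re-exports or inconsistent statistics) the supply
#' is clamped at zero and the shortfall reported as a warning.
#'
#' @param production,exports tonnes (non-negative; vectorised).
#' @return Non-negative tonnes.
#' @export
domesticSupply <- function(production, exports) {
  if (any(production < 0) || any(exports < 0))
    stop("production and exports must be non-negative", call. = FALSE)
  short <- exports - production
  if (any(short > 0))
    warning(sprintf(
      "exports exceed production (re-exports?): supply clamped at 0, total shortfall %.6g t",
      sum(short[short > 0])
    ), call. = FALSE)
  pmax(production - exports, 0)
}

#' National supply: production plus imports minus exports
#'
#' The standard apparent-consumption identity. A negative balance is
#' clamped at zero with a warning.
#'
#' @param production,imports,exports tonnes (non-negative; vectorised).
#' @return Non-negative tonnes.
#' @export
consumption <- function(production, imports, exports) {
  if (any(production < 0) || any(imports < 0) || any(exports < 0))
    stop("production, imports and exports must be non-negative",
         call. = FALSE)
  s <- production + imports - exports
  if (any(s < 0)) {
    warning(sprintf(
      "exports exceed production + imports: supply clamped at 0, total shortfall %.6g t",
      -sum(s[s < 0])
    ), call. = FALSE)
    s <- pmax(s, 0)
  }
  s
}

#' Convert trade tonnes to dry weight
#'
#' Trade statistics report fresh tonnes; the consumption pressure mixes
#' trade flows additively with production-based terms, so both must share
#' one weight basis. Multiplies each flow by `1 - water_pct/100`.
#'
#' @param trade a [TradeTable-class] (fresh tonnes).
#' @param waterTable data.frame with `crop_id`, `water_pct` covering every
#'   crop in the table.
#' @return A [TradeTable-class] in dry tonnes.
#' @export
tradeToDry <- function(trade, waterTable) {
  f <- trade@flows
  if (nrow(f)) f$tonnes <- f$tonnes * dryFactor(f$crop, waterTable)
  tradeTable(f)
}

#' Split a country's supply of a crop into domestic and imported tonnes
#'
#' @param focal focal country id.
#' @param crop crop id.
#' @param production the focal country's production of the crop (tonnes).
#' @param trade a [TradeTable-class] on the same weight basis as
#'   `production`.
#' @return List with `domestic` (production minus exports, clamped at 0)
#'   and `imported` (summed import flows into the focal country).
#' @export
splitSupply <- function(focal, crop, production, trade) {
  f <- trade@flows
  f <- f[f$crop == crop, , drop = FALSE]
  exports <- sum(f$tonnes[f$origin == focal])
  imports <- sum(f$tonnes[f$destination == focal])
  list(domestic = domesticSupply(production, exports), imported = imports)
}

#' Consumption-side biodiversity pressure (BP_cons)
#'
#' The pressure embedded in a focal country's consumption of a crop:
#' \deqn{BP_{cons} = C^{dom} \times BP_{fc} + \sum_i T_i \times BP_i}
#' the domestic supply times the focal country's per-tonne BP, plus each
#' import flow times the origin country's production-weighted BP. Import
#' tonnes from origins lacking a BP value (the origin grows none of the
#' crop in the data) contribute nothing and accumulate in
#' `unattributedImportTonnes` -- they are reported, never silently
#' dropped.
#'
#' @param focal focal country id.
#' @param crop crop id.
#' @param supply the focal country's domestic supply of the crop in
#'   tonnes (from [domesticSupply()] or [splitSupply()]), on the same
#'   weight basis as the BP table.
#' @param bpTable data.frame with columns `country`, `crop`, `bp_mean`
#'   (from [countryCropMetrics()]).
#' @param trade a [TradeTable-class] on the matching weight basis (see
#'   [tradeToDry()]).
#' @return A [ConsumptionPressure-class].
#' @examples
#' bpTab <- data.frame(country = c("FOC", "AAA"), crop = "apple",
#'                     bp_mean = c(2, 3))
#' tr <- tradeTable(data.frame(origin = "AAA", destination = "FOC",
#'                             crop = "apple", tonnes = 5))
#' bpConsTotal(bpCons("FOC", "apple", 10, bpTab, tr)) # 10*2 + 5*3 = 35
#' @export
bpCons <- function(focal, crop, supply, bpTable, trade) {
  stopifnot(is(trade, "TradeTable"), supply >= 0)
  tab <- bpTable[bpTable$crop == crop, , drop = FALSE]
  lookupBP <- function(ctry) {
    i <- match(ctry, tab$country)
    ifelse(is.na(i), NA_real_, tab$bp_mean[i])
  }
  bpFc <- lookupBP(focal)
  if (supply > 0 && is.na(bpFc))
    stop(sprintf(
      "no BP available for focal country %s, crop %s, with positive domestic supply",
      focal, crop
    ), call. = FALSE)
  domTerm <- if (supply > 0) supply * bpFc else 0

  f <- trade@flows
  f <- f[f$crop == crop & f$destination == focal & f$tonnes > 0, ,
         drop = FALSE]
  impTerms <- numeric(0)
  unattributed <- 0
  if (nrow(f)) {
    bpO <- lookupBP(f$origin)
    known <- !is.na(bpO)
    unattributed <- sum(f$tonnes[!known])
    impTerms <- f$tonnes[known] * bpO[known]
    names(impTerms) <- f$origin[known]
    impTerms <- impTerms[order(names(impTerms))]
  }
  new("ConsumptionPressure",
    focal = focal, crop = crop,
    domesticSupply = as.numeric(supply),
    domesticTerm = as.numeric(domTerm),
    importTerms = impTerms,
    bpCons = as.numeric(domTerm + sum(impTerms)),
    unattributedImportTonnes = as.numeric(unattributed)
  )
}

#' Read / write bilateral trade tables
#'
#' CSV with columns `origin`, `destination`, `crop`, `tonnes`; country
#' ids are ISO alpha-3 style strings.
#'
#' @param path CSV file path.
#' @return [readTradeTable()] returns a [TradeTable-class];
#'   [writeTradeTable()] returns `path` invisibly.
#' @export
readTradeTable <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  tradeTable(f)
}

#' @rdname readTradeTable
#' @param trade a [TradeTable-class].
#' @export
writeTradeTable <- function(trade, path) {
  writeStableCSV(trade@flows, path, numCols = "tonnes")
  invisible(path)
}
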