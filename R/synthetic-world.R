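#' @include AllClasses.R io.R zonal.R pressure.R
NULL

# Named substreams fanned out from one root seed: adding a new field to
# the generator never perturbs existing draws.
SUBSTREAM_OFFSETS <- c(
  richness = 11L, countries = 37L, water = 67L, trade = 53L, crops = 101L
)

subSeed <- function(seed, stream, k = 0L) {
  off <- SUBSTREAM_OFFSETS[[stream]] + k
  as.integer((as.double(seed) * 1009 + as.double(off) * 9176) %%
               (2^31 - 1))
}

# Separable Gaussian smoothing with edge replication; used to give the
# synthetic richness and yield surfaces spatial autocorrelation.
smoothMatrix <- function(M, half = 2L, sigma = 1.2) {
  w <- stats::dnorm(seq(-half, half), sd = sigma)
  w <- w / sum(w)
  along1 <- function(A) {
    out <- 0
    n <- nrow(A)
    for (k in seq(-half, half)) {
      i <- pmin(pmax(seq_len(n) + k, 1L), n)
      out <- out + w[k + half + 1L] * A[i, , drop = FALSE]
    }
    out
  }
  t(along1(t(along1(M))))
}

rescaleTo <- function(M, lo, hi) {
  r <- range(M)
  if (r[2] > r[1]) (M - r[1]) / (r[2] - r[1]) * (hi - lo) + lo
  else matrix((lo + hi) / 2, nrow(M), ncol(M))
}

# ISO alpha-3 style synthetic country ids: AAA, AAB, ...
alpha3Ids <- function(n) {
  vapply(seq_len(n) - 1L, function(k) {
    paste0(LETTERS[k %/% 676L + 1L], LETTERS[(k %/% 26L) %% 26L + 1L],
           LETTERS[k %% 26L + 1L])
  }, "")
}

#' Configure the synthetic world generator
#'
#' Defaults describe the standard test world: a coarse 24 x 48 global
#' equal-angle grid (7.5-degree cells), 3 contiguous countries, 4 crops,
#' spatially autocorrelated richness between 10 and 200 species, about a
#' third of cells cultivated per crop, fresh yields of 2--20 t/ha,
#' fruit/vegetable-like water contents of 70--95%, and trade flows on
#' about 40% of feasible partner pairs.
#'
#' @param grid analysis [GridSpec-class].
#' @param nCountries,nCrops counts.
#' @param richnessRange integer richness range (species per cell).
#' @param cropSparsity fraction of cells with positive harvested area.
#' @param yieldRange fresh yield range, t/ha.
#' @param waterRange water-content range, percent.
#' @param tradeDensity fraction of feasible (origin, destination, crop)
#'   triples carrying a flow.
#' @param seed root seed.
#' @return A [WorldConfig-class].
#' @export
worldConfig <- function(grid = gridSpec(24, 48, cellSize = 7.5),
                        nCountries = 3, nCrops = 4,
                        richnessRange = c(10, 200),
                        cropSparsity = 0.35,
                        yieldRange = c(2, 20),
                        waterRange = c(70, 95),
                        tradeDensity = 0.4,
                        seed = 1) {
  new("WorldConfig",
    grid = grid, nCountries = as.integer(nCountries),
    nCrops = as.integer(nCrops),
    richnessRange = as.numeric(richnessRange),
    cropSparsity = as.numeric(cropSparsity),
    yieldRange = as.numeric(yieldRange),
    waterRange = as.numeric(waterRange),
    tradeDensity = as.numeric(tradeDensity), seed = as.integer(seed)
  )
}

# Contiguous countries grown by repeated frontier accretion from random
# seed cells; a cell reachable by several countries in the same round
# goes to the lowest country id.
growCountries <- function(spec, nCountries, seed) {
  nr <- spec@nRows
  nc <- spec@nCols
  set.seed(subSeed(seed, "countries"))
  lab <- matrix(NA_integer_, nr, nc)
  lab[sample.int(nr * nc, nCountries)] <- seq_len(nCountries)
  repeat {
    if (!anyNA(lab)) break
    claimed <- !is.na(lab)
    newLab <- lab
    for (k in seq_len(nCountries)) {
      reg <- !is.na(lab) & lab == k
      nb <- matrix(FALSE, nr, nc)
      nb[-1, ] <- nb[-1, ] | reg[-nr, ]
      nb[-nr, ] <- nb[-nr, ] | reg[-1, ]
      nb[, -1] <- nb[, -1] | reg[, -nc]
      nb[, -nc] <- nb[, -nc] | reg[, -1]
      take <- nb & !claimed
      newLab[take] <- k
      claimed <- claimed | take
    }
    if (identical(newLab, lab)) break  # cannot happen on a connected grid
    lab <- newLab
  }
  lab
}

#' Generate a seeded synthetic world
#'
#' Produces a small self-consistent set of inputs emulating the
#' statistical shape of global crop, species-range and trade data:
#' per-crop sparse non-negative harvested-area surfaces bounded by the
#' spherical cell area, smooth positive yield surfaces, a spatially
#' autocorrelated integer richness surface, a contiguous-country
#' partition of the grid, a per-crop water-content table, and sparse
#' non-negative bilateral trade flows whose origins are restricted to
#' countries actually producing the crop and whose exports never exceed
#' production. Deterministic for a fixed seed.
#'
#' @param config a [WorldConfig-class].
#' @return List with elements `crops` (named list of [CropData-class]),
#'   `richness` ([Layer-class], units `"species"`), `zones`
#'   ([CountryZones-class]), `water` (data.frame `crop_id`, `water_pct`),
#'   `trade` ([TradeTable-class], fresh tonnes), `countryIds`, `config`.
#' @export
generateWorld <- function(config = worldConfig()) {
  stopifnot(is(config, "WorldConfig"))
  validObject(config)
  spec <- config@grid
  nr <- spec@nRows
  nc <- spec@nCols
  seed <- config@seed

  set.seed(subSeed(seed, "richness"))
  sr <- smoothMatrix(matrix(stats::rnorm(nr * nc), nr, nc))
  sr <- round(rescaleTo(sr, config@richnessRange[1],
                        config@richnessRange[2]))
  richness <- layer(spec, sr, units = "species")

  lab <- growCountries(spec, config@nCountries, seed)
  countryIds <- alpha3Ids(config@nCountries)
  zones <- zonesFromLabels(layer(spec, lab + 0, units = ""), countryIds)

  ca <- cellArea(spec)@values
  cropIds <- sprintf("crop%02d", seq_len(config@nCrops))
  set.seed(subSeed(seed, "water"))
  water <- data.frame(
    crop_id = cropIds,
    water_pct = stats::runif(config@nCrops, config@waterRange[1],
                             config@waterRange[2]),
    stringsAsFactors = FALSE
  )

  crops <- lapply(seq_len(config@nCrops), function(ci) {
    set.seed(subSeed(seed, "crops", ci))
    grown <- stats::runif(nr * nc) < config@cropSparsity
    frac <- stats::rbeta(nr * nc, 2, 5)
    ha <- matrix(ifelse(grown, frac, 0), nr, nc) * ca
    yl <- rescaleTo(smoothMatrix(matrix(stats::rnorm(nr * nc), nr, nc)),
                    config@yieldRange[1], config@yieldRange[2])
    cropData(cropIds[ci], layer(spec, ha, units = "ha"),
             layer(spec, yl, units = "t ha-1"), water$water_pct[ci])
  })
  names(crops) <- cropIds

  # trade: origins restricted to producers; per-origin exports are a
  # share of its fresh production, so no clamping can fire downstream
  set.seed(subSeed(seed, "trade"))
  rows <- list()
  for (ci in seq_len(config@nCrops)) {
    pTot <- countrySum(computeProduction(crops[[ci]], dry = FALSE), zones)
    for (o in countryIds[pTot[countryIds] > 0]) {
      dest <- setdiff(countryIds, o)
      pick <- dest[stats::runif(length(dest)) < config@tradeDensity]
      if (!length(pick)) next
      share <- stats::runif(1, 0.1, 0.6)
      u <- stats::runif(length(pick))
      rows[[length(rows) + 1L]] <- data.frame(
        origin = o, destination = pick, crop = cropIds[ci],
        tonnes = share * pTot[[o]] * u / sum(u),
        stringsAsFactors = FALSE
      )
    }
  }
  trade <- if (length(rows)) tradeTable(do.call(rbind, rows))
           else tradeTable()

  list(crops = crops, richness = richness, zones = zones, water = water,
       trade = trade, countryIds = countryIds, config = config)
}

#' Generate a world with prescribed country-level BP values
#'
#' Constructs harvested area, yield and richness so that every country's
#' true production-weighted BP equals its target exactly, for every crop:
#' yield is 1 t/ha everywhere, water content 0 (dry equals fresh), and
#' richness is uniform within each country at the target value, so each
#' cell's BP is `SR / yield = target` and any production weighting
#' returns the same number. Harvested area is arbitrary positive. Used
#' for parameter-recovery testing of the whole pipeline.
#'
#' @param targets positive per-country BP targets; names are country ids
#'   (unnamed values are assigned to the generated ids in order). Length
#'   must equal `config@nCountries`. Non-integer targets yield a
#'   real-valued richness surface, which downstream operations accept.
#' @param config a [WorldConfig-class].
#' @return A world list as from [generateWorld()] plus a `truth` element
#'   (named per-country BP) ; the trade table is empty.
#' @export
generateKnownBPWorld <- function(targets, config = worldConfig()) {
  stopifnot(is(config, "WorldConfig"))
  if (length(targets) != config@nCountries)
    stop("need one BP target per country", call. = FALSE)
  if (any(targets <= 0)) stop("targets must be positive", call. = FALSE)
  spec <- config@grid
  nr <- spec@nRows
  nc <- spec@nCols
  lab <- growCountries(spec, config@nCountries, config@seed)
  countryIds <- alpha3Ids(config@nCountries)
  if (is.null(names(targets))) names(targets) <- countryIds
  if (!setequal(names(targets), countryIds))
    stop("target names must match the generated country ids: ",
         paste(countryIds, collapse = ", "), call. = FALSE)
  zones <- zonesFromLabels(layer(spec, lab + 0, units = ""), countryIds)
  richness <- layer(spec,
    matrix(as.numeric(targets[countryIds[lab]]), nr, nc),
    units = "species")

  ca <- cellArea(spec)@values
  cropIds <- sprintf("crop%02d", seq_len(config@nCrops))
  crops <- lapply(seq_len(config@nCrops), function(ci) {
    set.seed(subSeed(config@seed, "crops", ci))
    ha <- matrix(stats::runif(nr * nc, 0.05, 0.5), nr, nc) * ca
    cropData(cropIds[ci], layer(spec, ha, units = "ha"),
             layer(spec, 1, units = "t ha-1"), 0)
  })
  names(crops) <- cropIds
  water <- data.frame(crop_id = cropIds, water_pct = 0,
                      stringsAsFactors = FALSE)
  list(crops = crops, richness = richness, zones = zones, water = water,
       trade = tradeTable(), countryIds = countryIds, config = config,
       truth = targets[countryIds])
}

#' Write / read a complete world fixture directory
#'
#' Serialises a generated world to plain-text files: per-crop ASCII-grid
#' pairs (`<crop>_ha.asc`, `<crop>_yield.asc`), `richness.asc`,
#' `zones.csv`, `water.csv`, `trade.csv`, and `manifest.yml` recording
#' the configuration and seed.
#'
#' @param world a world list from [generateWorld()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cr in world$crops) {
    writeAsciiGrid(cr@harvestedArea,
                   file.path(dir, paste0(cr@cropId, "_ha.asc")))
    writeAsciiGrid(cr@yield,
                   file.path(dir, paste0(cr@cropId, "_yield.asc")))
  }
  writeAsciiGrid(world$richness, file.path(dir, "richness.asc"))
  writeZonesCSV(world$zones, file.path(dir, "zones.csv"))
  writeStableCSV(world$water, file.path(dir, "water.csv"),
                 numCols = "water_pct")
  writeTradeTable(world$trade, file.path(dir, "trade.csv"))
  cfg <- world$config
  yaml::write_yaml(list(
    grid = list(
      nrows = cfg@grid@nRows, ncols = cfg@grid@nCols,
      cellsize = cfg@grid@cellSize, origin_lon = cfg@grid@originLon,
      origin_lat = cfg@grid@originLat
    ),
    n_countries = cfg@nCountries, n_crops = cfg@nCrops,
    richness_range = cfg@richnessRange, crop_sparsity = cfg@cropSparsity,
    yield_range = cfg@yieldRange, water_range = cfg@waterRange,
    trade_density = cfg@tradeDensity, seed = cfg@seed,
    crops = names(world$crops), countries = world$countryIds
  ), file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname writeWorld
#' @export
readWorld <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  water <- readWaterTable(file.path(dir, "water.csv"))
  crops <- lapply(man$crops, function(id) {
    cropData(id,
      readAsciiGrid(file.path(dir, paste0(id, "_ha.asc")), units = "ha"),
      readAsciiGrid(file.path(dir, paste0(id, "_yield.asc")),
                    units = "t ha-1"),
      water$water_pct[match(id, water$crop_id)]
    )
  })
  names(crops) <- man$crops
  list(
    crops = crops,
    richness = readAsciiGrid(file.path(dir, "richness.asc"),
                             units = "species"),
    zones = readZonesCSV(file.path(dir, "zones.csv")),
    water = water,
    trade = readTradeTable(file.path(dir, "trade.csv")),
    countryIds = man$countries,
    config = worldConfig(
      grid = gridSpec(man$grid$nrows, man$grid$ncols,
                      cellSize = man$grid$cellsize,
                      originLon = man$grid$origin_lon,
                      originLat = man$grid$origin_lat),
      nCountries = man$n_countries, nCrops = man$n_crops,
      richnessRange = unlist(man$richness_range),
      cropSparsity = man$crop_sparsity,
      yieldRange = unlist(man$yield_range),
      waterRange = unlist(man$water_range),
      tradeDensity = man$trade_density, seed = man$seed
    )
  )
}
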