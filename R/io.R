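#' @include grid-geometry.R
NULL

#' Read and write layers as ESRI ASCII grids
#'
#' Plain-text single-band raster exchange. The header records the grid
#' geometry (corner registration, row 1 northmost) and an explicit nodata
#' value; masked cells are written as the nodata token. Values are
#' written with 17 significant digits so that doubles round-trip.
#'
#' @param path file path (conventionally `.asc`).
#' @param units unit tag to attach on read (the format itself carries
#'   none).
#' @return [readAsciiGrid()] returns a [Layer-class]; [writeAsciiGrid()]
#'   returns `path` invisibly.
#' @export
readAsciiGrid <- function(path, units = "") {
  ln <- readLines(path, n = 6L)
  kv <- strsplit(trimws(ln), "[[:space:]]+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% key))
    stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  nr <- as.integer(val["nrows"])
  nc <- as.integer(val["ncols"])
  v <- scan(path, what = double(), skip = 6L, quiet = TRUE,
            na.strings = format(val["nodata_value"]))
  if (length(v) != nr * nc)
    stop("expected ", nr * nc, " values, found ", length(v), call. = FALSE)
  v[v == val["nodata_value"]] <- NA_real_
  m <- matrix(v, nr, nc, byrow = TRUE)
  spec <- gridSpec(nr, nc,
    cellSize = val["cellsize"], originLon = val["xllcorner"],
    originLat = val["yllcorner"] + nr * val["cellsize"]
  )
  layer(spec, m, units = units)
}

#' @rdname readAsciiGrid
#' @param x a [Layer-class].
#' @param nodata value written for masked cells.
#' @export
writeAsciiGrid <- function(x, path, nodata = -9999) {
  stopifnot(is(x, "Layer"))
  sp <- x@spec
  fmt <- function(z) sprintf("%.17g", z)
  hdr <- c(
    paste("ncols", sp@nCols),
    paste("nrows", sp@nRows),
    paste("xllcorner", fmt(sp@originLon)),
    paste("yllcorner", fmt(sp@originLat - sp@nRows * sp@cellSize)),
    paste("cellsize", fmt(sp@cellSize)),
    paste("NODATA_value", fmt(nodata))
  )
  v <- x@values
  if (any(v == nodata, na.rm = TRUE))
    stop("layer contains the nodata value ", nodata, call. = FALSE)
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Deterministic CSV writer: fixed column order, numeric columns in
# scientific notation with 9 significant digits, byte-stable across runs.
writeStableCSV <- function(df, path, numCols = NULL, meta = NULL) {
  if (is.null(numCols)) numCols <- names(df)[vapply(df, is.double, TRUE)]
  for (cn in numCols) {
    z <- df[[cn]]
    s <- sprintf("%.9e", z)
    s[is.na(z)] <- ""  # missing stays empty, never 0
    df[[cn]] <- s
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  invisible(path)
}

#' Read / write country-zone tables
#'
#' Zones are exchanged as CSV with columns `country`, `cell` (linear cell
#' index on the stated grid) and `coverage`; the grid geometry travels in
#' `# key: value` comment lines so the mapping is self-describing.
#'
#' @param path CSV file path.
#' @return [readZonesCSV()] returns a [CountryZones-class].
#' @export
readZonesCSV <- function(path) {
  ln <- readLines(path)
  metaLn <- grep("^# ", ln, value = TRUE)
  meta <- list()
  for (m in sub("^# ", "", metaLn)) {
    kv <- strsplit(m, ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  need <- c("nrows", "ncols", "cellsize", "origin_lon", "origin_lat")
  if (!all(need %in% names(meta)))
    stop("zones CSV lacks grid metadata (", paste(need, collapse = ", "),
         ")", call. = FALSE)
  z <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  spec <- gridSpec(
    as.integer(meta$nrows), as.integer(meta$ncols),
    cellSize = as.numeric(meta$cellsize),
    originLon = as.numeric(meta$origin_lon),
    originLat = as.numeric(meta$origin_lat)
  )
  countryZones(spec, z)
}

#' @rdname readZonesCSV
#' @param zones a [CountryZones-class].
#' @export
writeZonesCSV <- function(zones, path) {
  sp <- zones@spec
  meta <- list(
    nrows = sp@nRows, ncols = sp@nCols,
    cellsize = sprintf("%.17g", sp@cellSize),
    origin_lon = sprintf("%.17g", sp@originLon),
    origin_lat = sprintf("%.17g", sp@originLat)
  )
  z <- zones@zones[order(zones@zones$country, zones@zones$cell), ,
                   drop = FALSE]
  writeStableCSV(z, path, numCols = "coverage", meta = meta)
  invisible(path)
}

#' Convert a country-label layer to zones
#'
#' All-or-nothing coverage from a labelled raster: every unmasked cell
#' belongs wholly (coverage 1) to the country given by its label.
#'
#' @param labels a [Layer-class] of numeric country labels (`NA` = no
#'   country).
#' @param countryIds character vector mapping label value `k` to
#'   `countryIds[k]`.
#' @return A [CountryZones-class].
#' @export
zonesFromLabels <- function(labels, countryIds) {
  v <- labels@values
  cells <- which(!is.na(v))
  countryZones(labels@spec, data.frame(
    country = countryIds[v[cells]], cell = cells, coverage = 1,
    stringsAsFactors = FALSE
  ))
}
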