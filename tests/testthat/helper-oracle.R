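# Independent brute-force oracles: plain double loops over zone entries
# and trade records, written against the raw matrices only. They share no
# code path with the package's vectorised implementations.

oracleMetrics <- function(world, dry = TRUE, tol = 1e-9) {
  z <- zonesTable(world$zones)
  sr <- layerValues(world$richness)
  rows <- list()
  for (cr in world$crops) {
    ha <- layerValues(cr@harvestedArea)
    yl <- layerValues(cr@yield)
    f <- if (dry) 1 - cr@waterPct / 100 else 1
    for (ctry in sort(unique(z$country))) {
      zz <- z[z$country == ctry, , drop = FALSE]
      pTot <- aTot <- num <- den <- 0
      for (r in seq_len(nrow(zz))) {
        cell <- zz$cell[r]
        cov <- zz$coverage[r]
        p <- yl[cell] * ha[cell] * f
        asr <- ha[cell] * sr[cell]
        if (!is.na(p)) pTot <- pTot + cov * p
        if (!is.na(asr)) aTot <- aTot + cov * asr
        if (!is.na(p) && !is.na(asr) && p >= tol) {
          num <- num + cov * p * (asr / p)
          den <- den + cov * p
        }
      }
      bpM <- if (den > 0) num / den else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        country = ctry, crop = cr@cropId, production_total = pTot,
        asr_total = aTot, bp_mean = bpM,
        bp_prod = if (is.na(bpM)) NA_real_ else bpM * pTot,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$crop, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Direct summation of the consumption decomposition from its definition.
oracleBPCons <- function(focal, crop, supply, bpTable, trade) {
  tab <- bpTable[bpTable$crop == crop, , drop = FALSE]
  bpOf <- function(ctry) {
    i <- which(tab$country == ctry)
    if (length(i)) tab$bp_mean[i] else NA_real_
  }
  total <- if (supply > 0) supply * bpOf(focal) else 0
  f <- tradeFlows(trade)
  for (r in seq_len(nrow(f))) {
    if (f$crop[r] != crop || f$destination[r] != focal) next
    b <- bpOf(f$origin[r])
    if (!is.na(b)) total <- total + f$tonnes[r] * b
  }
  total
}

relErr <- function(x, y) {
  d <- abs(x - y)
  s <- pmax(abs(x), abs(y))
  ifelse(s > 0, d / s, d)
}

# Tiny single-grid world builder for targeted unit tests.
tinyWorld <- function(nr = 3, nc = 4, seed = 42, water = 20) {
  sp <- gridSpec(nr, nc, cellSize = 10, originLon = 0,
                 originLat = nr * 10 / 2)
  set.seed(seed)
  ca <- layerValues(cellArea(sp))
  ha <- matrix(runif(nr * nc, 0, 0.5), nr, nc) * ca
  yl <- matrix(runif(nr * nc, 1, 8), nr, nc)
  sr <- matrix(sample(0:40, nr * nc, replace = TRUE), nr, nc)
  crop <- cropData("veg01", layer(sp, ha, "ha"), layer(sp, yl, "t ha-1"),
                   water)
  half <- floor(nr * nc / 2)
  zones <- countryZones(sp, data.frame(
    country = rep(c("AAA", "AAB"), c(half, nr * nc - half)),
    cell = seq_len(nr * nc), coverage = 1
  ))
  list(crops = list(veg01 = crop), richness = layer(sp, sr, "species"),
       zones = zones,
       water = data.frame(crop_id = "veg01", water_pct = water),
       trade = tradeTable(), countryIds = c("AAA", "AAB"))
}
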