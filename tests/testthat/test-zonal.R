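test_that("countrySum handles full and fractional coverage", {
  sp <- gridSpec(1, 2, cellSize = 1, originLon = 0, originLat = 1)
  ly <- layer(sp, matrix(c(3, 4), 1), "t")
  full <- countryZones(sp, data.frame(country = "AAA", cell = 1:2,
                                      coverage = 1))
  expect_equal(unname(countrySum(ly, full)), 7)

  half <- countryZones(sp, data.frame(country = "AAA", cell = 1,
                                      coverage = 0.5))
  ten <- layer(sp, matrix(c(10, 0), 1), "t")
  expect_equal(unname(countrySum(ten, half)), 5)
})

test_that("countrySum matches a brute-force loop on a random partition", {
  sp <- gridSpec(15, 15, cellSize = 2, originLon = 0, originLat = 15)
  set.seed(21)
  v <- matrix(rnorm(225, 50, 20), 15)
  v[sample(225, 20)] <- NA
  ly <- layer(sp, v)
  # random fractional partition: up to two countries share a cell
  ids <- c("AAA", "AAB", "AAC", "AAD")
  zrows <- do.call(rbind, lapply(seq_len(225), function(cell) {
    k <- sample(ids, sample(1:2, 1))
    covs <- if (length(k) == 1) runif(1, 0.2, 1)
            else {c1 <- runif(1, 0.1, 0.9); c(c1, runif(1, 0, 1 - c1))}
    data.frame(country = k, cell = cell, coverage = covs)
  }))
  cz <- countryZones(sp, zrows)
  got <- countrySum(ly, cz)
  for (ctry in ids) {
    want <- 0
    zz <- zrows[zrows$country == ctry, ]
    for (r in seq_len(nrow(zz))) {
      val <- v[zz$cell[r]]
      if (!is.na(val)) want <- want + zz$coverage[r] * val
    }
    expect_lt(abs(got[[ctry]] - want), 1e-12 * max(1, abs(want)))
  }
})

test_that("countryBP is the production-weighted mean of cell BP", {
  sp <- gridSpec(1, 2, cellSize = 1, originLon = 0, originLat = 1)
  cz <- countryZones(sp, data.frame(country = "AAA", cell = 1:2,
                                    coverage = 1))
  bp <- layer(sp, matrix(c(1, 3), 1), "species.ha t-1")
  expect_equal(unname(countryBP(bp, layer(sp, matrix(c(1, 1), 1), "t"),
                                cz)), 2)
  expect_equal(unname(countryBP(bp, layer(sp, matrix(c(3, 1), 1), "t"),
                                cz)), 1.5)
  # zero production -> missing, not 0
  expect_true(is.na(unname(countryBP(bp, layer(sp, 0, "t"), cz))))
})

test_that("uniform richness gives BP = SR x sum(HA) / sum(P)", {
  w <- tinyWorld(4, 5, seed = 31)
  sp <- gridOf(w$crops[[1]])
  srStar <- 17
  rich <- layer(sp, srStar, "species")
  cr <- w$crops[[1]]
  p <- computeProduction(cr)
  bp <- computeBP(cr, rich, production = p)
  got <- countryBP(bp, p, w$zones)
  haTot <- countrySum(cr@harvestedArea, w$zones)
  pTot <- countrySum(p, w$zones)
  expect_lt(max(relErr(got, srStar * haTot / pTot)), 1e-12)
})

test_that("bp_prod equals bp_mean x production and the ASR total", {
  expect_equal(bpProd(2.5, 4), 10)
  expect_true(is.na(bpProd(NA_real_, 4)))

  w <- tinyWorld(5, 6, seed = 33)
  m <- countryCropMetrics(w$crops, w$richness, w$zones)
  expect_lt(max(relErr(m$bp_prod, m$bp_mean * m$production_total)), 1e-9)
  asrTot <- countrySum(computeASR(w$crops[[1]], w$richness), w$zones)
  expect_lt(max(relErr(m$bp_prod, asrTot[m$country])), 1e-9)
  # bp_mean bounded by cell BP extrema over the country's cells
  bp <- layerValues(computeBP(w$crops[[1]], w$richness))
  z <- zonesTable(w$zones)
  for (ctry in unique(z$country)) {
    cells <- z$cell[z$country == ctry]
    b <- bp[cells]
    expect_gte(m$bp_mean[m$country == ctry], min(b, na.rm = TRUE) - 1e-12)
    expect_lte(m$bp_mean[m$country == ctry], max(b, na.rm = TRUE) + 1e-12)
  }
})

test_that("splitting a country preserves sums and weighted-mean BP", {
  w <- tinyWorld(4, 6, seed = 35)
  sp <- gridOf(w$crops[[1]])
  cells <- seq_len(24)
  union <- countryZones(sp, data.frame(country = "UUU", cell = cells,
                                       coverage = 1))
  parts <- countryZones(sp, data.frame(
    country = rep(c("PPA", "PPB"), c(10, 14)), cell = cells, coverage = 1
  ))
  p <- computeProduction(w$crops[[1]])
  asr <- computeASR(w$crops[[1]], w$richness)
  bp <- computeBP(w$crops[[1]], w$richness, production = p)
  expect_lt(relErr(sum(countrySum(asr, parts)),
                   unname(countrySum(asr, union))), 1e-12)
  bpU <- unname(countryBP(bp, p, union))
  bpP <- countryBP(bp, p, parts)
  # production weights of the parts (over BP-unmasked cells)
  wts <- vapply(c("PPA", "PPB"), function(ctry) {
    cl <- zonesTable(parts)$cell[zonesTable(parts)$country == ctry]
    sum(layerValues(p)[cl][!is.na(layerValues(bp)[cl])])
  }, 0)
  expect_lt(relErr(bpU, sum(bpP * wts) / sum(wts)), 1e-12)
})

test_that("country BP is scale-free in production units", {
  w <- tinyWorld(4, 4, seed = 37)
  cr <- w$crops[[1]]
  p <- computeProduction(cr)
  bp <- computeBP(cr, w$richness, production = p)
  k <- 7.3
  pk <- layer(gridOf(cr), k * layerValues(p), "t")
  bpk <- layer(gridOf(cr), layerValues(computeASR(cr, w$richness)) /
                 layerValues(pk), "species.ha t-1")
  expect_lt(max(relErr(countryBP(bpk, pk, w$zones) * k,
                       countryBP(bp, p, w$zones))), 1e-12)
})

test_that("ranking is dense-descending with lexicographic tie order", {
  t1 <- rankEntities(data.frame(id = c("a", "b", "c"), v = c(5, 7, 5)),
                     "v", "id")
  expect_equal(t1$rank, c(1, 2, 2))
  expect_equal(t1$id, c("b", "a", "c"))
  expect_equal(rankEntities(data.frame(id = "x", v = 1), "v", "id")$rank, 1)
  expect_error(rankEntities(data.frame(id = "x", v = 1), "nope", "id"),
               "unknown metric")

  set.seed(41)
  tab <- data.frame(id = sprintf("e%03d", 1:100),
                    v = sample(round(rnorm(60, 50, 10), 1), 100, TRUE))
  got <- rankEntities(tab, "v", "id")
  want <- match(got$v, sort(unique(tab$v), decreasing = TRUE))
  expect_equal(got$rank, want)
  expect_false(is.unsorted(got$rank))
})
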