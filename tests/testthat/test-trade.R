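test_that("domestic supply subtracts exports and clamps at zero", {
  expect_equal(domesticSupply(10, 4), 6)
  expect_warning(s <- domesticSupply(3, 5), "clamped")
  expect_equal(s, 0)
  expect_equal(domesticSupply(7, 0), 7)
  expect_error(domesticSupply(-1, 0), "non-negative")
})

test_that("consumption follows production + imports - exports", {
  expect_equal(consumption(10, 5, 3), 12)
  expect_equal(consumption(0, 5, 0), 5)
  expect_equal(consumption(10, 0, 10), 0)
  expect_warning(consumption(1, 0, 5), "clamped")
  expect_error(consumption(1, -2, 0), "non-negative")
})

test_that("trade tables validate their invariants", {
  expect_error(tradeTable(data.frame(origin = "AAA", destination = "AAA",
                                     crop = "c", tonnes = 1)), "differ")
  expect_error(tradeTable(data.frame(origin = "AAA", destination = "AAB",
                                     crop = "c", tonnes = -1)),
               "non-negative")
  dup <- data.frame(origin = "AAA", destination = "AAB", crop = "c",
                    tonnes = c(1, 2))
  expect_error(tradeTable(dup), "one record")
  expect_silent(tradeTable())
})

test_that("bpCons reproduces the two-term decomposition", {
  bpTab <- data.frame(country = c("FOC", "AAA"), crop = "apple",
                      bp_mean = c(2, 3))
  tr <- tradeTable(data.frame(origin = "AAA", destination = "FOC",
                              crop = "apple", tonnes = 5))
  cp <- bpCons("FOC", "apple", 10, bpTab, tr)
  expect_equal(bpConsTotal(cp), 35)
  expect_equal(domesticTerm(cp), 20)
  expect_equal(unname(importTerms(cp)), 15)

  # zero-import limit
  cp0 <- bpCons("FOC", "apple", 10, bpTab, tradeTable())
  expect_equal(bpConsTotal(cp0), 10 * 2)
  expect_length(importTerms(cp0), 0)

  # missing focal BP with positive supply is an error; with zero supply
  # the domestic term vanishes cleanly
  bpNoFoc <- data.frame(country = "AAA", crop = "apple", bp_mean = 3)
  expect_error(bpCons("FOC", "apple", 10, bpNoFoc, tr), "focal")
  expect_equal(bpConsTotal(bpCons("FOC", "apple", 0, bpNoFoc, tr)), 15)

  # unattributed origins are reported, not dropped
  tr2 <- tradeTable(data.frame(
    origin = c("AAA", "ZZZ"), destination = "FOC", crop = "apple",
    tonnes = c(5, 8)
  ))
  cp2 <- bpCons("FOC", "apple", 10, bpTab, tr2)
  expect_equal(unattributedImports(cp2), 8)
  expect_equal(bpConsTotal(cp2), 35)
})

test_that("bpCons matches direct summation on random trade tables", {
  set.seed(51)
  ids <- c("FOC", "AAA", "AAB", "AAC")
  for (rep in 1:20) {
    bpTab <- data.frame(country = ids, crop = "c",
                        bp_mean = runif(4, 0.1, 60))
    pairs <- expand.grid(origin = ids, destination = "FOC",
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$origin != "FOC", ]
    pairs$crop <- "c"
    pairs$tonnes <- runif(3, 0, 1e4)
    tr <- tradeTable(pairs)
    supply <- runif(1, 0, 1e4)
    got <- bpConsTotal(bpCons("FOC", "c", supply, bpTab, tr))
    want <- oracleBPCons("FOC", "c", supply, bpTab, tr)
    expect_lt(relErr(got, want), 1e-12)
  }
})

test_that("bpCons is linear, monotone and bounded", {
  set.seed(53)
  ids <- c("FOC", "AAA", "AAB")
  bpTab <- data.frame(country = ids, crop = "c",
                      bp_mean = runif(3, 0.5, 20))
  tr <- tradeTable(data.frame(origin = c("AAA", "AAB"),
                              destination = "FOC", crop = "c",
                              tonnes = c(40, 11)))
  supply <- 25
  base <- bpConsTotal(bpCons("FOC", "c", supply, bpTab, tr))
  # linearity in tonnes
  k <- 3.7
  trK <- tradeTable(transform(tradeFlows(tr), tonnes = tonnes * k))
  expect_lt(relErr(bpConsTotal(bpCons("FOC", "c", k * supply, bpTab, trK)),
                   k * base), 1e-12)
  # adding a positive-BP import never decreases the total
  bpTab2 <- rbind(bpTab, data.frame(country = "AAC", crop = "c",
                                    bp_mean = 5))
  trPlus <- tradeTable(rbind(tradeFlows(tr), data.frame(
    origin = "AAC", destination = "FOC", crop = "c", tonnes = 2
  )))
  expect_gte(bpConsTotal(bpCons("FOC", "c", supply, bpTab2, trPlus)), base)
  # bound by total tonnage times the largest BP involved
  expect_lte(base, (supply + sum(tradeFlows(tr)$tonnes)) *
               max(bpTab$bp_mean))
})

test_that("supply splits into domestic and imported tonnes", {
  tr <- tradeTable(data.frame(
    origin = c("FOC", "AAA", "AAB"), destination = c("AAA", "FOC", "FOC"),
    crop = "c", tonnes = c(2, 3, 1)
  ))
  s <- splitSupply("FOC", "c", 10, tr)
  expect_equal(s$domestic, 8)
  expect_equal(s$imported, 4)
  expect_equal(splitSupply("FOC", "c", 10, tradeTable()),
               list(domestic = 10, imported = 0))
  expect_warning(s0 <- splitSupply("FOC", "c", 0, tr), "clamped")
  expect_equal(s0$domestic, 0)
  expect_equal(s0$imported, 4)
})

test_that("dry conversion of trade preserves the flow structure", {
  tr <- tradeTable(data.frame(origin = c("AAA", "AAB"),
                              destination = "FOC", crop = c("a", "b"),
                              tonnes = c(10, 10)))
  wt <- data.frame(crop_id = c("a", "b"), water_pct = c(90, 50))
  dryTr <- tradeToDry(tr, wt)
  expect_equal(tradeFlows(dryTr)$tonnes, c(1, 5))
  expect_error(tradeToDry(tr, wt[1, , drop = FALSE]), "missing")
})

test_that("closed-world conservation: summed BP_cons equals attributed supply", {
  # on a closed world with every BP defined and no clamping, summing the
  # consumption pressure over all focal countries attributes each
  # country's entire supply at its own BP
  w <- generateWorld(worldConfig(seed = 19))
  m <- countryCropMetrics(w$crops, w$richness, w$zones)
  trade <- tradeToDry(w$trade, w$water)
  for (id in names(w$crops)) {
    tot <- 0
    attributed <- 0
    for (fc in w$countryIds) {
      p <- m$production_total[m$country == fc & m$crop == id]
      s <- splitSupply(fc, id, p, trade)
      tot <- tot + bpConsTotal(bpCons(fc, id, s$domestic, m, trade))
    }
    # every tonne of origin i's production is consumed somewhere at BP_i:
    # (P_i - E_i) at home plus E_i abroad, so the total is sum BP_i * P_i
    for (ctry in w$countryIds) {
      p <- m$production_total[m$country == ctry & m$crop == id]
      bp <- m$bp_mean[m$country == ctry & m$crop == id]
      attributed <- attributed + bp * p
    }
    expect_lt(relErr(tot, attributed), 1e-9)
  }
})
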