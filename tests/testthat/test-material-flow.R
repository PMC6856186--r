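# Flux ledgers, mass-balance closure, and trade attribution.

test_that("hg_flux bridges Mg/yr and ng/g to kg/yr", {
  expect_equal(hg_flux(1, 100), 1e-4)
  expect_equal(hg_flux(0, 123), 0)
  # order-of-magnitude consistency with the global mid-2010s grain flux
  expect_equal(hg_flux(7.4e8, 7.16), 5298.4, tolerance = 0.01)
  expect_error(hg_flux(-1, 1), "mass")
  expect_error(hg_flux(1, -1), "concentration")
})

test_that("autarky food flux uses the country's own concentration", {
  sheets <- tibble::tibble(country = "A", year = 2013, production = 100,
                           import = 0, stock_variation = 0, export = 0,
                           feed = 0, seed = 0, processing = 0,
                           other_uses = 0, food = 70, losses = 30)
  conc <- tibble::tibble(country = "A", thg_ng_g = 10, mehg_ng_g = 2)
  led <- build_ledger(sheets, conc)
  fd <- led$food[led$food$species == "MeHg", ]
  expect_equal(fd$food_kg, 70 * 2 * 1e-6)
  expect_equal(fd$food_import_kg, 0)
})

test_that("a single-source importer is fully attributed to its partner", {
  sheets <- tibble::tibble(
    country = c("I", "E"), year = 2013,
    production = c(0, 100), import = c(10, 0), stock_variation = 0,
    export = c(0, 10), feed = 0, seed = 0, processing = 0, other_uses = 0,
    food = c(10, 90), losses = 0)
  conc <- tibble::tibble(country = c("I", "E"), thg_ng_g = c(5, 10),
                         mehg_ng_g = c(1, 2))
  trade <- tibble::tibble(reporter = "E", partner = "I", quantity_Mg = 10)
  led <- build_ledger(sheets, conc, trade)
  fd <- led$food[led$food$species == "MeHg" & led$food$country == "I", ]
  expect_equal(fd$food_kg, 10 * 2 * 1e-6)  # partner's concentration
  expect_equal(fd$food_import_kg / fd$food_kg, 1)
})

test_that("the three-country ledger matches the hand-computed oracle", {
  led <- build_ledger(three_country_sheets(), three_country_conc(),
                      three_country_trade())
  f <- led$fluxes[led$fluxes$species == "THg", ]
  fx <- function(cc, tm) f$flux_kg[f$country == cc & f$term == tm]
  # hand arithmetic (spreadsheet): pool A = 60*10 + 10*20 = 800 mg over 70 Mg
  expect_equal(fx("A", "production"), 100 * 10 * 1e-6)
  expect_equal(fx("A", "import"), 10 * 20 * 1e-6)
  expect_equal(fx("A", "export"), 40 * 10 * 1e-6)
  expect_equal(fx("A", "food"), 56 * (8e-4 / 70) , tolerance = 1e-12)
  expect_equal(fx("B", "stock_variation"), 5 * 20 * 1e-6)
  expect_equal(fx("B", "food"), 180 * (4.2e-3 / 225), tolerance = 1e-12)
  expect_equal(fx("C", "food"), 1e-4, tolerance = 1e-12)
  fd <- led$food[led$food$species == "THg", ]
  expect_equal(fd$food_import_kg[fd$country == "A"], 0.25 * 6.4e-4,
               tolerance = 1e-12)
  expect_equal(fd$food_import_kg[fd$country == "B"], 3.36e-3 / 14,
               tolerance = 1e-12)
  expect_equal(fd$food_import_kg[fd$country == "C"], 1e-4, tolerance = 1e-12)
  share <- trade_embodied_share(led, species = "THg")$global
  expect_equal(share, 5e-4 / 4.1e-3, tolerance = 1e-12)
})

test_that("ledger closure holds and perturbations are reported", {
  sheets <- three_country_sheets()
  led <- build_ledger(sheets, three_country_conc(), three_country_trade())
  bal <- check_balance(led)
  expect_true(all(bal$pass))
  expect_true(all(abs(bal$residual_kg) < 1e-12))

  sheets$food[1] <- sheets$food[1] + 1  # +1 Mg food breaks the sheet
  led2 <- build_ledger(sheets, three_country_conc(), three_country_trade())
  bal2 <- check_balance(led2)
  a_thg <- bal2[bal2$country == "A" & bal2$species == "THg", ]
  expect_false(a_thg$pass)
  # residual = -1 Mg at the pooled concentration of A (800/70 ng/g)
  expect_equal(a_thg$residual_kg, -1 * (8e-4 / 70), tolerance = 1e-12)

  zero <- three_country_sheets()
  for (tm in balance_terms()) zero[[tm]] <- 0
  bal3 <- check_balance(build_ledger(zero, three_country_conc(),
                                     trade = NULL))
  expect_true(all(bal3$residual_kg == 0))
})

test_that("exports and import-origin fluxes conserve mercury globally", {
  led <- build_ledger(three_country_sheets(), three_country_conc(),
                      three_country_trade())
  for (sp in c("THg", "MeHg")) {
    f <- led$fluxes[led$fluxes$species == sp, ]
    expect_equal(sum(f$flux_kg[f$term == "export"]),
                 sum(f$flux_kg[f$term == "import"]), tolerance = 1e-15)
    bi <- led$bilateral[led$bilateral$species == sp, ]
    expect_equal(sum(bi$flux_kg), sum(f$flux_kg[f$term == "export"]),
                 tolerance = 1e-15)
  }
})

test_that("fluxes are homogeneous of degree one in concentrations", {
  conc <- three_country_conc()
  led1 <- build_ledger(three_country_sheets(), conc, three_country_trade())
  conc2 <- conc
  conc2$thg_ng_g <- 3 * conc2$thg_ng_g
  conc2$mehg_ng_g <- 3 * conc2$mehg_ng_g
  led3 <- build_ledger(three_country_sheets(), conc2, three_country_trade())
  expect_equal(led3$fluxes$flux_kg, 3 * led1$fluxes$flux_kg,
               tolerance = 1e-12)
})

test_that("trade-embodied share spans its extremes", {
  # no trade anywhere -> 0
  sheets <- tibble::tibble(country = c("A", "B"), year = 2013,
                           production = c(10, 20), import = 0,
                           stock_variation = 0, export = 0, feed = 0,
                           seed = 0, processing = 0, other_uses = 0,
                           food = c(10, 20), losses = 0)
  conc <- tibble::tibble(country = c("A", "B"), thg_ng_g = c(1, 2),
                         mehg_ng_g = c(1, 2))
  expect_equal(trade_embodied_share(build_ledger(sheets, conc))$global, 0)
  # all food imported everywhere (two countries swapping production)
  sheets2 <- tibble::tibble(country = c("A", "B"), year = 2013,
                            production = c(10, 20), import = c(20, 10),
                            stock_variation = 0, export = c(10, 20),
                            feed = 0, seed = 0, processing = 0,
                            other_uses = 0, food = c(20, 10), losses = 0)
  trade2 <- tibble::tibble(reporter = c("A", "B"), partner = c("B", "A"),
                           quantity_Mg = c(10, 20))
  expect_equal(trade_embodied_share(build_ledger(sheets2, conc, trade2))$global,
               1)
  # zero denominator -> 0 with a warning
  zero <- sheets; zero$food <- 0; zero$losses <- c(10, 20)
  czero <- conc; czero$thg_ng_g <- 0; czero$mehg_ng_g <- 0
  expect_warning(s <- trade_embodied_share(build_ledger(zero, czero))$global,
                 "defined as 0")
  expect_equal(s, 0)
})

test_that("trade delta matches the autarky counterfactual arithmetic", {
  # importer sources half its food mass from a partner with 3x its conc
  sheets <- tibble::tibble(
    country = c("I", "P"), year = 2013,
    production = c(50, 150), import = c(50, 0), stock_variation = 0,
    export = c(0, 50), feed = 0, seed = 0, processing = 0, other_uses = 0,
    food = c(100, 100), losses = 0)
  conc <- tibble::tibble(country = c("I", "P"), thg_ng_g = c(1, 3),
                         mehg_ng_g = c(1, 3))
  trade <- tibble::tibble(reporter = "P", partner = "I", quantity_Mg = 50)
  led <- build_ledger(sheets, conc, trade)
  td <- trade_delta(led, sheets, conc)
  expect_equal(td$delta[td$country == "I"], 1, tolerance = 1e-12)  # +100%
  # the pure exporter with equal concentrations sees delta 0 (<= 0)
  expect_lte(td$delta[td$country == "P"], 1e-12)
  # importer whose partner matches its own concentration: delta 0
  conc_eq <- tibble::tibble(country = c("I", "P"), thg_ng_g = c(3, 3),
                            mehg_ng_g = c(3, 3))
  td0 <- trade_delta(build_ledger(sheets, conc_eq, trade), sheets, conc_eq)
  expect_equal(td0$delta[td0$country == "I"], 0, tolerance = 1e-12)
})

test_that("countries without production fall back to the regional mean", {
  led <- build_ledger(three_country_sheets(), three_country_conc(),
                      three_country_trade())
  td <- trade_delta(led, three_country_sheets(), three_country_conc())
  expect_false(td$defined[td$country == "C"])  # no production, no region
  regions <- tibble::tibble(country = c("A", "B", "C"), region = "R1")
  td2 <- trade_delta(led, three_country_sheets(), three_country_conc(),
                     regions = regions)
  # regional production-weighted MeHg conc = (100*2 + 200*4)/300 = 10/3
  expect_equal(td2$counterfactual_kg[td2$country == "C"],
               10 * (10 / 3) * 1e-6, tolerance = 1e-12)
  # actual food MeHg in C: 10 Mg imported from A at 2 ng/g -> 2e-5 kg
  expect_equal(td2$delta[td2$country == "C"], 2e-5 / (10 * (10 / 3) * 1e-6) - 1,
               tolerance = 1e-12)
})

test_that("trade rows naming unknown countries are rejected", {
  trade <- tibble::tibble(reporter = "A", partner = "ZZ", quantity_Mg = 1)
  expect_error(
    build_ledger(three_country_sheets(), three_country_conc(), trade),
    "unknown countries")
})
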