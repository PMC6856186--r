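# The synthetic-world generator: internal consistency, determinism,
# ground-truth recovery, calibration.

test_that("generated worlds close exactly and pass every reader validation", {
  for (seed in c(1, 7)) {
    w <- generate_world(world_config(n_countries = 20, seed = seed))
    expect_true(all(check_sheet_closure(w$sheets, tol = 1e-12)$pass))
    # trade row sums equal export terms exactly
    rs <- rowsum(w$trade$quantity_Mg, w$trade$reporter)
    exp_term <- setNames(w$sheets$export, w$sheets$country)
    expect_equal(as.numeric(rs), unname(exp_term[rownames(rs)]),
                 tolerance = 1e-15)
    # the file set round-trips through the validating readers
    dir <- tempfile()
    write_world(w, dir)
    back <- read_world(dir)
    expect_equal(back$sheets$production, w$sheets$production,
                 tolerance = 1e-12)
    expect_true(all(check_sheet_closure(back$sheets, tol = 1e-7)$pass))
    expect_true(all(back$records$included))
  }
})

test_that("the same seed reproduces the world bit for bit", {
  w1 <- generate_world(world_config(seed = 42))
  w2 <- generate_world(world_config(seed = 42))
  expect_identical(w1$sheets, w2$sheets)
  expect_identical(w1$records, w2$records)
  expect_identical(w1$truth, w2$truth)
  w3 <- generate_world(world_config(seed = 43))
  expect_false(identical(w1$sheets$production, w3$sheets$production))
})

test_that("a two-country world without trade is autarkic and closed", {
  w <- generate_world(world_config(n_countries = 2, trade_intensity = 0,
                                   seed = 3))
  expect_null(w$trade)
  expect_true(all(w$sheets$export == 0))
  expect_true(all(w$sheets$import == 0))
  expect_true(all(check_sheet_closure(w$sheets, tol = 1e-12)$pass))
})

test_that("analyzer recovers the generator's trade-embodied share exactly", {
  for (seed in c(2, 9)) {
    w <- generate_world(world_config(n_countries = 25, seed = seed))
    led <- build_ledger(w$sheets, w$truth$concentrations, w$trade)
    share <- trade_embodied_share(led, species = "MeHg")$global
    expect_equal(share, w$truth$trade_embodied_share_mehg, tolerance = 1e-12)
  }
})

test_that("the spatial field's variogram range is recoverable", {
  # recovery simulation: range estimates from a single 200-point
  # realization are highly variable, so check the geometric mean of the
  # fitted range over several generated fields against the generating
  # 2000 km (within 50%)
  ranges <- vapply(1:6, function(s) {
    cfg <- world_config(n_countries = 200, spatial_range_km = 2000,
                        measured_frac = 1, seed = s)
    w <- generate_world(cfg)
    samples <- tibble::tibble(lat = w$countries$lat, lon = w$countries$lon,
                              value = log(w$truth$concentrations$thg_ng_g))
    fit_variogram(samples)$range
  }, numeric(1))
  gm <- exp(mean(log(ranges)))
  expect_gt(gm, 1000)
  expect_lt(gm, 3000)
})

test_that("calibration pins the deterministic global grain THg", {
  w <- generate_world(world_config(seed = 5))
  cal <- calibrate_to_paper(w, target_mg = 5.3)
  flux <- sum(cal$sheets$production * cal$truth$concentrations$thg_ng_g) * 1e-6
  expect_equal(flux, 5300, tolerance = 1e-9)
  # doubling the target doubles every production mass
  cal2 <- calibrate_to_paper(w, target_mg = 10.6)
  expect_equal(cal2$sheets$production, 2 * cal$sheets$production,
               tolerance = 1e-12)
  # sheets stay closed after calibration
  expect_true(all(check_sheet_closure(cal$sheets, tol = 1e-9)$pass))
})

test_that("contaminated surveys obey the inclusion rule and the site law", {
  s <- generate_contaminated_survey("gold_mining", n = 3, seed = 1)
  expect_equal(nrow(s), 6L)  # paired THg and MeHg rows
  expect_error(generate_contaminated_survey("gold_mining", n = 2),
               "at least 3")
  expect_error(generate_contaminated_survey("background", n = 5),
               "contaminated")
  # a large survey recovers the generating contaminated-site power law
  big <- generate_contaminated_survey("hg_mining", n = 400, seed = 2)
  thg <- big$median_ng_g[big$species == "THg"]
  mehg <- big$median_ng_g[big$species == "MeHg"]
  fit <- fit_power_law(thg, mehg)
  law <- mehg_power_law("hg_mining")
  expect_equal(fit$b, law$b, tolerance = 0.05)
  expect_equal(fit$a, law$a, tolerance = 0.15)
})

test_that("contaminated medians sit far above the background field", {
  s <- generate_contaminated_survey("smelting", n = 50, seed = 4,
                                    background_median = 7)
  thg <- s$median_ng_g[s$species == "THg"]
  # multiplier is 10-100x, so the survey median should exceed 10x background
  expect_gt(median(thg), 70)
})
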