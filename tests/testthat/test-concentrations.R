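# Record sampling, species imputation, power-law fitting, pooling.

test_that("sample_median degenerates to the median when gsd is 1", {
  expect_equal(sample_median(10, gsd = 1, n = 20), rep(10, 20))
  expect_error(sample_median(-1), "positive")
})

test_that("sampled medians centre on the record median", {
  set.seed(11)
  x <- sample_median(10, gsd = 2, n = 1e5)
  expect_equal(median(x), 10, tolerance = 0.02)  # oracle: lognormal quantile
  expect_true(all(x > 0))
})

test_that("records without a reported SD use the 65% default dispersion", {
  g <- default_gsd()
  expect_equal(g, exp(log(1.65) / qnorm(0.975)))
  set.seed(4)
  x <- sample_median(10, gsd = NA, n = 1e5)
  # 95% of draws within median * [1/1.65, 1.65] under the default mapping
  inside <- mean(x > 10 / 1.65 & x < 10 * 1.65)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("MeHg imputation reproduces the fitted power laws", {
  expect_equal(impute_mehg_from_thg(1, "background"), 0.80)
  expect_equal(impute_mehg_from_thg(0, "background"), 0)
  expect_equal(impute_mehg_from_thg(10, "background"), 0.80 * 10^0.65,
               tolerance = 1e-12)
  expect_equal(impute_mehg_from_thg(1, "gold_mining"), 0.74)
  expect_error(impute_mehg_from_thg(-1), "nonnegative")
})

test_that("imputation is strictly increasing and inverts analytically", {
  x <- seq(0, 50, by = 0.5)
  y <- impute_mehg_from_thg(x)
  expect_true(all(diff(y) > 0))
  expect_equal(y[1], 0)  # continuous at the origin
  thg <- c(0.5, 5, 50)
  expect_equal(impute_thg_from_mehg(impute_mehg_from_thg(thg)), thg,
               tolerance = 1e-12)
})

test_that("noise-free power-law fits recover the generating coefficients", {
  for (ab in list(c(0.8, 0.65), c(0.27, 1.1), c(3, 0.5))) {
    x <- exp(seq(log(0.5), log(80), length.out = 40))
    y <- ab[1] * x^ab[2]
    fit <- suppressWarnings(fit_power_law(x, y))  # perfect-fit note
    expect_equal(fit$a, ab[1], tolerance = 1e-6)
    expect_equal(fit$b, ab[2], tolerance = 1e-6)
  }
})

test_that("degenerate power-law inputs are rejected", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(fit_power_law(rep(2, 10), runif(10, 1, 2)), "zero variance")
  expect_error(fit_power_law(c(1, 2, 0), c(1, 2, 3)), "positive")
})

test_that("noisy fits cover the true exponent at roughly the stated rate", {
  # simulation oracle: with correct SEs, the 1-SE interval should cover the
  # true slope ~68% of the time; require at least 60% over 100 seeds
  law <- mehg_power_law("background")
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- exp(runif(200, log(1), log(100)))
    y <- law$a * x^law$b * rlnorm(200, 0, 0.6)
    fit <- fit_power_law(x, y)
    abs(fit$b - law$b) <= fit$b_se
  }, logical(1))
  expect_gte(mean(hits), 0.60)
})

test_that("record validation applies the inclusion rules", {
  recs <- dplyr::bind_rows(
    make_record("R1", n = 10),
    make_record("R2", n = 2),          # too few samples
    make_record("R3", year = 1995))    # before the cutoff
  v <- validate_records(recs)
  expect_equal(v$included, c(TRUE, FALSE, FALSE))
  expect_error(validate_records(make_record(median_ng_g = -2)), "positive")
  expect_error(validate_records(make_record(gsd = 0.9)), "gsd")
  expect_error(validate_records(make_record(site_class = "volcano")),
               "site_class")
})

test_that("country pooling takes the n-weighted median of record medians", {
  recs <- dplyr::bind_rows(
    make_record("R1", median_ng_g = 10, n = 3),
    make_record("R2", median_ng_g = 20, n = 30),
    make_record("R3", median_ng_g = 30, n = 3),
    make_record("R4", country = "B", median_ng_g = 5, n = 5),
    make_record("R5", site_class = "gold_mining", median_ng_g = 900, n = 50))
  p <- pool_country_records(recs)
  expect_equal(p$median_ng_g[p$country == "A"], 20)  # weight sits on R2
  expect_equal(p$median_ng_g[p$country == "B"], 5)
  expect_false(any(p$median_ng_g > 100))  # contaminated record excluded
})

test_that("national surfaces use records, imputation, then kriging", {
  recs <- dplyr::bind_rows(
    make_record("R1", country = "A", lat = 0, lon = 0, median_ng_g = 10),
    make_record("R2", country = "A", lat = 0, lon = 0, species = "MeHg",
                median_ng_g = 2),
    make_record("R3", country = "B", lat = 10, lon = 10, median_ng_g = 40))
  targets <- tibble::tibble(country = c("A", "B", "C"),
                            lat = c(0, 10, 5), lon = c(0, 10, 5))
  conc <- country_grain_concentration(recs, targets)
  expect_equal(conc$thg_ng_g[conc$country == "A"], 10)
  expect_equal(conc$mehg_ng_g[conc$country == "A"], 2)
  # B has THg only: MeHg through the background power law
  expect_equal(conc$mehg_ng_g[conc$country == "B"], 0.80 * 40^0.65,
               tolerance = 1e-9)
  # C unmeasured: kriged between A and B, so within their range
  expect_gte(conc$thg_ng_g[conc$country == "C"], 10)
  expect_lte(conc$thg_ng_g[conc$country == "C"], 40)
})

test_that("a single measured country propagates to all others", {
  recs <- make_record("R1", country = "A", median_ng_g = 12)
  targets <- tibble::tibble(country = c("A", "Z"), lat = c(0, 30),
                            lon = c(0, 60))
  conc <- country_grain_concentration(recs, targets)
  expect_equal(conc$thg_ng_g, c(12, 12))
  expect_error(
    country_grain_concentration(make_record(n = 1), targets),
    "no usable")
})
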