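# Distribution specs, the Monte Carlo engine, and envelope properties.

test_that("point masses and degenerate draws behave deterministically", {
  expect_equal(draw_dist(dist_point(5), 10), rep(5, 10))
  env <- run_mc(function(d) c(y = d$x + 1), list(x = dist_point(2)),
                n_draws = 50, seed = 1)
  expect_equal(env$median, 3)
  expect_equal(env$q25, 3)
  expect_equal(env$q75, 3)
})

test_that("bernoulli draws hit the causal-association probability", {
  set.seed(42)
  x <- draw_dist(dist_bernoulli(1 / 3), 1e5)
  se <- sqrt(1 / 3 * 2 / 3 / 1e5)
  expect_lt(abs(mean(x) - 1 / 3), 3 * se)
  expect_true(all(x %in% c(0, 1)))
})

test_that("uniform 30%-deviation draws respect the half-width bounds", {
  set.seed(7)
  x <- draw_dist(dist_uniform_cv30(100), 1e4)
  expect_true(all(x >= 70 & x <= 130))
  # strict-CV reading widens the interval so that CV = 0.30
  y <- draw_dist(dist_uniform_cv30(100, "strict_cv"), 1e5)
  expect_equal(sd(y) / mean(y), 0.30, tolerance = 0.02)
})

test_that("lognormal envelope median matches the analytic quantile", {
  env <- run_mc(function(d) c(y = d$x),
                list(x = dist_lognormal(10, 2)), n_draws = 5000, seed = 3)
  expect_equal(env$median, 10, tolerance = 0.05)
  expect_true(env$q25 < env$median && env$median < env$q75)
})

test_that("truncated normal draws never cross the bound", {
  set.seed(1)
  x <- draw_dist(dist_normal_trunc(0.5, 2, lower = 0), 1e4)
  expect_true(all(x >= 0))
  expect_error(dist_normal_trunc(-1, 1, lower = 0), "truncation")
  expect_error(dist_lognormal(-1, 2), "positive")
  expect_error(dist_bernoulli(1.5), "probability")
})

test_that("identical seeds give bit-identical envelopes", {
  specs <- list(x = dist_lognormal(5, 1.5), m = dist_uniform_cv30(100))
  model <- function(d) c(flux = d$x * d$m)
  e1 <- run_mc(model, specs, n_draws = 400, seed = 99)
  e2 <- run_mc(model, specs, n_draws = 400, seed = 99)
  expect_identical(e1, e2)
})

test_that("adding an input does not perturb existing sub-streams", {
  e1 <- run_mc(function(d) c(u = d$a),
               list(a = dist_lognormal(3, 2)), n_draws = 300, seed = 5)
  e2 <- run_mc(function(d) c(u = d$a, v = d$b),
               list(a = dist_lognormal(3, 2), b = dist_uniform_cv30(10)),
               n_draws = 300, seed = 5)
  expect_identical(e1[e1$output == "u", c("median", "q25", "q75")],
                   e2[e2$output == "u", c("median", "q25", "q75")])
})

test_that("monotone models commute with envelope quantiles", {
  # odd draw count: the median is an exact order statistic, so a strictly
  # monotone transform commutes with it exactly
  env <- run_mc(function(d) c(y = exp(d$x), x = d$x),
                list(x = dist_lognormal(2, 1.5)), n_draws = 4001, seed = 8)
  med_x <- env$median[env$output == "x"]
  med_y <- env$median[env$output == "y"]
  expect_equal(med_y, exp(med_x), tolerance = 1e-9)  # same draws, exact
  expect_equal(med_y, exp(2), tolerance = 0.35)      # analytic, MC error
})

test_that("excess model failures abort with diagnostics", {
  bad <- function(d) if (d$x > 0.5) stop("boom") else c(y = d$x)
  expect_error(
    run_mc(bad, list(x = dist_uniform_cv30(1)), n_draws = 200, seed = 1),
    "draws failed")
})

test_that("envelopes round-trip through JSON", {
  env <- run_mc(function(d) c(a = d$x, b = 2 * d$x),
                list(x = dist_lognormal(1, 2)), n_draws = 100, seed = 2)
  path <- tempfile(fileext = ".json")
  write_envelopes(env, path)
  back <- read_envelopes(path)
  expect_equal(back$median, env$median, tolerance = 1e-12)
  expect_equal(back$output, env$output)
})
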