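# Synthetic-world generator: complete, internally consistent inputs with
# the statistical structure the pipeline assumes, plus latent ground truth
# emitted on the side (never read by the analysis path).

#' Configuration of a synthetic world
#'
#' Defaults emulate the structure of the real inputs: a log-normal
#' background grain THg field (median 7 ng/g, geometric SD 2) with
#' exponential spatial autocorrelation; MeHg tied to THg through the
#' background power law; a tenth of production exported; 80% of domestic
#' supply eaten as food; populations log-uniform between 1e5 and 1e9.
#'
#' @param n_countries Number of countries (>= 2).
#' @param n_regions Number of regions countries are grouped into.
#' @param conc_median,conc_gsd Background grain THg field parameters (ng/g).
#' @param spatial_range_km Range of the exponential spatial correlation.
#' @param contaminated_multiplier Log-uniform range of the contaminated-site
#'   concentration multiplier.
#' @param trade_intensity Fraction of production exported (in `[0, 1)`).
#' @param food_share Food share of domestic supply (in `(0, 1]`).
#' @param measured_frac Fraction of countries with grain THg records.
#' @param mehg_frac Fraction of measured countries that also report MeHg.
#' @param record_noise_gsd Geometric SD of the sampling noise on record
#'   medians around the latent national value.
#' @param pop_range Population range (log-uniform).
#' @param percap_range Per-capita rice production range, Mg/person/yr.
#' @param year Analysis year stamped on the sheets.
#' @param seed Integer seed; the whole world is a deterministic function
#'   of the configuration.
#' @return Object of class `ricehg_world_config`.
#' @export
world_config <- function(n_countries = 30L, n_regions = 5L,
                         conc_median = 7, conc_gsd = 2,
                         spatial_range_km = 2000,
                         contaminated_multiplier = c(10, 100),
                         trade_intensity = 0.1, food_share = 0.8,
                         measured_frac = 0.7, mehg_frac = 0.6,
                         record_noise_gsd = 1.2,
                         pop_range = c(1e5, 1e9),
                         percap_range = c(0.03, 0.15),
                         year = 2013L, seed = 1L) {
  stopifnot(n_countries >= 2L, n_regions >= 1L, conc_median > 0,
            conc_gsd >= 1, trade_intensity >= 0, trade_intensity < 1,
            food_share > 0, food_share <= 1,
            measured_frac > 0, measured_frac <= 1)
  if (trade_intensity + food_share > 1 && trade_intensity >= 1) {
    stop("infeasible configuration", call. = FALSE)
  }
  structure(list(n_countries = as.integer(n_countries),
                 n_regions = as.integer(n_regions),
                 conc_median = conc_median, conc_gsd = conc_gsd,
                 spatial_range_km = spatial_range_km,
                 contaminated_multiplier = contaminated_multiplier,
                 trade_intensity = trade_intensity, food_share = food_share,
                 measured_frac = measured_frac, mehg_frac = mehg_frac,
                 record_noise_gsd = record_noise_gsd,
                 pop_range = pop_range, percap_range = percap_range,
                 year = as.integer(year), seed = as.integer(seed)),
            class = "ricehg_world_config")
}

# Gaussian random field on country centroids with exponential covariance.
spatial_lognormal_field <- function(coords, median, gsd, range_km) {
  d <- great_circle_km(coords)
  sigma2 <- log(gsd)^2
  S <- sigma2 * exp(-d / range_km) + diag(1e-10, nrow(d))
  L <- t(chol(S))
  exp(log(median) + as.numeric(L %*% stats::rnorm(nrow(d))))
}

#' Generate a complete synthetic world
#'
#' Produces every input table the pipeline reads -- concentration records,
#' balance sheets, bilateral trade matrix, demographics, health baselines,
#' fate fractions, enrichment series, residue nitrogen totals -- plus the
#' latent ground truth (true national concentrations and the true
#' trade-embodied MeHg share, computed by the generator's own arithmetic).
#' Balance sheets close exactly and trade-matrix row sums equal the export
#' terms exactly by construction. Deterministic under the config seed.
#'
#' @param config A `ricehg_world_config`.
#' @return Object of class `ricehg_world`: list with `config`, `countries`,
#'   `records`, `sheets`, `trade`, `demographics`, `baselines`, `fates`,
#'   `enrichment`, `residues`, `truth`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "ricehg_world_config"))
  set.seed(config$seed)
  n <- config$n_countries
  cc <- sprintf("C%03d", seq_len(n))

  countries <- tibble::tibble(
    country = cc,
    lat = stats::runif(n, -35, 45),
    lon = stats::runif(n, -170, 170)
  )
  # contiguous longitude bands make regions spatially coherent
  band <- ceiling(rank(countries$lon, ties.method = "first") /
                    (n / config$n_regions))
  countries$region <- sprintf("R%02d", pmin(band, config$n_regions))
  continents <- names(continent_body_weights())
  countries$continent <- continents[(as.integer(factor(countries$region)) - 1L) %%
                                      length(continents) + 1L]

  thg_true <- spatial_lognormal_field(countries, config$conc_median,
                                      config$conc_gsd,
                                      config$spatial_range_km)
  bg <- mehg_power_law("background")
  mehg_true <- bg$a * thg_true^bg$b

  # --- concentration records -------------------------------------------
  n_meas <- max(2L, round(config$measured_frac * n))
  measured <- sort(sample(n, n_meas))
  recs <- list()
  rid <- 0L
  for (i in measured) {
    rid <- rid + 1L
    recs[[length(recs) + 1L]] <- tibble::tibble(
      record_id = sprintf("REC%04d", rid), country = cc[i],
      lat = countries$lat[i], lon = countries$lon[i],
      site_class = "background", organ = "grain", species = "THg",
      median_ng_g = thg_true[i] *
        stats::rlnorm(1, 0, log(config$record_noise_gsd)),
      gsd = 1.5, n = sample(5:50, 1L), year = config$year)
  }
  with_mehg <- measured[stats::runif(n_meas) < config$mehg_frac]
  for (i in with_mehg) {
    rid <- rid + 1L
    recs[[length(recs) + 1L]] <- tibble::tibble(
      record_id = sprintf("REC%04d", rid), country = cc[i],
      lat = countries$lat[i], lon = countries$lon[i],
      site_class = "background", organ = "grain", species = "MeHg",
      median_ng_g = mehg_true[i] *
        stats::rlnorm(1, 0, log(config$record_noise_gsd)),
      gsd = 1.5, n = sample(5:50, 1L), year = config$year)
  }
  records <- dplyr::bind_rows(recs)

  # --- demographics, baselines -----------------------------------------
  population <- exp(stats::runif(n, log(config$pop_range[1]),
                                 log(config$pop_range[2])))
  demographics <- tibble::tibble(
    country = cc, continent = countries$continent,
    population = round(population),
    body_weight_kg = unname(continent_body_weights()[countries$continent]))
  baselines <- tibble::tibble(
    country = cc,
    fatal_heart_attacks_ge30 = round(demographics$population * 0.002 *
                                       stats::runif(n, 0.5, 1.5)))

  # --- balance sheets and trade ----------------------------------------
  percap <- stats::runif(n, config$percap_range[1], config$percap_range[2])
  production <- demographics$population * percap
  export <- config$trade_intensity * production *
    stats::runif(n, 0.5, 1.5)
  export <- pmin(export, 0.5 * production)
  stock_variation <- production * stats::runif(n, -0.03, 0.03)

  trade <- NULL
  if (config$trade_intensity > 0) {
    rows <- list()
    for (j in seq_len(n)) {
      if (export[j] <= 0) next
      partners <- setdiff(seq_len(n), j)
      w <- demographics$population[partners]
      q <- export[j] * w / sum(w)
      q[length(q)] <- export[j] - sum(q[-length(q)])  # exact row sum
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reporter = cc[j], partner = cc[partners], quantity_Mg = q)
    }
    trade <- dplyr::bind_rows(rows)
  }
  import <- rep(0, n)
  if (!is.null(trade)) {
    agg <- rowsum(trade$quantity_Mg, trade$partner)
    idx <- match(cc, rownames(agg))
    import <- ifelse(is.na(idx), 0, agg[idx, 1])
  }

  supply <- production - export + stock_variation + import
  food <- config$food_share * supply
  rest <- supply - food
  feed <- 0.30 * rest; seed_t <- 0.20 * rest; processing <- 0.20 * rest
  other_uses <- 0.15 * rest
  losses <- supply - food - feed - seed_t - processing - other_uses  # exact

  sheets <- tibble::tibble(
    country = cc, year = config$year,
    production = production, import = import,
    stock_variation = stock_variation, export = export,
    feed = feed, seed = seed_t, processing = processing,
    other_uses = other_uses, food = food, losses = losses)

  # --- residues, fates, enrichment -------------------------------------
  rp <- residue_params()
  residues <- tibble::tibble(
    country = cc,
    residue_n_Mg = production * rp$straw_grain_ratio * rp$nitrogen_content)

  raw <- cbind(burned_field = stats::runif(n, 0.05, 0.20),
               feed = stats::runif(n, 0.10, 0.30),
               fertilizer = stats::runif(n, 0.10, 0.30),
               domestic_fuel = stats::runif(n, 0.05, 0.15),
               industrial_fuel = stats::runif(n, 0, 0.10),
               thatching = stats::runif(n, 0, 0.10))
  tot <- rowSums(raw)
  raw[tot > 0.95, ] <- raw[tot > 0.95, ] * 0.95 / tot[tot > 0.95]
  fates <- tibble::tibble(
    country = rep(cc, each = ncol(raw)),
    fate = rep(colnames(raw), times = n),
    fraction = as.numeric(t(raw)),
    scenario = "fao")

  growth <- stats::runif(config$n_regions, 0.005, 0.02)
  enrichment <- dplyr::bind_rows(lapply(seq_len(config$n_regions), function(r) {
    yrs <- 1961:2016
    tibble::tibble(region = sprintf("R%02d", r), year = yrs,
                   ef = exp(growth[r] * (yrs - 2013)))
  }))

  # --- ground truth (generator-side arithmetic, plain loops) ------------
  tot_food_hg <- 0; tot_food_import_hg <- 0
  for (j in seq_len(n)) {
    dom <- production[j] - export[j] + stock_variation[j]
    imp_hg <- 0; imp_mass <- 0
    if (!is.null(trade)) {
      into_j <- trade[trade$partner == cc[j], ]
      if (nrow(into_j) > 0L) {
        for (r in seq_len(nrow(into_j))) {
          k <- match(into_j$reporter[r], cc)
          imp_hg <- imp_hg + into_j$quantity_Mg[r] * mehg_true[k] * 1e-6
          imp_mass <- imp_mass + into_j$quantity_Mg[r]
        }
      }
    }
    pool_hg <- dom * mehg_true[j] * 1e-6 + imp_hg
    pool_mass <- dom + imp_mass
    if (pool_mass <= 0) next
    food_hg <- food[j] * pool_hg / pool_mass
    tot_food_hg <- tot_food_hg + food_hg
    if (pool_hg > 0) {
      tot_food_import_hg <- tot_food_import_hg + food_hg * imp_hg / pool_hg
    }
  }
  truth <- list(
    concentrations = tibble::tibble(country = cc, thg_ng_g = thg_true,
                                    mehg_ng_g = mehg_true),
    trade_embodied_share_mehg = if (tot_food_hg > 0)
      tot_food_import_hg / tot_food_hg else 0,
    global_grain_thg_kg = sum(production * thg_true * 1e-6),
    global_grain_mehg_kg = sum(production * mehg_true * 1e-6)
  )

  structure(list(config = config, countries = countries, records = records,
                 sheets = sheets, trade = trade, demographics = demographics,
                 baselines = baselines, fates = fates,
                 enrichment = enrichment, residues = residues, truth = truth),
            class = "ricehg_world")
}

#' Rescale a synthetic world so its global grain THg hits a target
#'
#' Multiplies every mass in the world (all balance-sheet terms, trade
#' flows, residue nitrogen) by a single factor so that the deterministic
#' global grain THg -- production weighted by the true national
#' concentrations -- equals `target_mg` megagrams. Default target 5.3 Mg,
#' the observed global magnitude for the mid-2010s. Populations and
#' concentrations are untouched, so concentration-side statistics (e.g. the
#' trade-embodied share) are invariant under calibration.
#'
#' @param world A `ricehg_world`.
#' @param target_mg Target global grain THg, Mg/yr.
#' @return The rescaled `ricehg_world`.
#' @export
calibrate_to_paper <- function(world, target_mg = 5.3) {
  stopifnot(inherits(world, "ricehg_world"), target_mg > 0)
  current_kg <- world$truth$global_grain_thg_kg
  if (current_kg <= 0) stop("world has zero global grain THg", call. = FALSE)
  s <- target_mg * 1000 / current_kg
  for (tm in balance_terms()) world$sheets[[tm]] <- world$sheets[[tm]] * s
  if (!is.null(world$trade)) {
    world$trade$quantity_Mg <- world$trade$quantity_Mg * s
  }
  world$residues$residue_n_Mg <- world$residues$residue_n_Mg * s
  world$truth$global_grain_thg_kg <- world$truth$global_grain_thg_kg * s
  world$truth$global_grain_mehg_kg <- world$truth$global_grain_mehg_kg * s
  world$calibration_factor <- s
  world
}

#' Generate a synthetic contaminated-site rice survey
#'
#' Paired THg and MeHg grain records from a contaminated area: THg medians
#' are background draws times a log-uniform multiplier; MeHg follows the
#' contaminated-site power law with multiplicative log-normal noise.
#'
#' @param site_class A contaminated site class (not `"background"`).
#' @param n Number of sites (>= 3, the inclusion rule).
#' @param seed Optional seed.
#' @param background_median,background_gsd Background THg field parameters.
#' @param multiplier Log-uniform multiplier range (default 10-100x).
#' @param noise_gsd Geometric SD of the MeHg residual noise.
#' @param country,lat,lon Location stamped on the records.
#' @return Records tibble with `2 n` rows (one THg and one MeHg row per
#'   site, sharing a site index in `record_id`).
#' @export
generate_contaminated_survey <- function(site_class = "gold_mining", n = 10L,
                                         seed = NULL,
                                         background_median = 7,
                                         background_gsd = 2,
                                         multiplier = c(10, 100),
                                         noise_gsd = 1.3,
                                         country = "XXC", lat = 0, lon = 0) {
  if (site_class == "background" || !site_class %in% SITE_CLASSES) {
    stop("site_class must be a contaminated class", call. = FALSE)
  }
  if (n < 3L) stop("surveys need at least 3 sites (inclusion rule)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mult <- exp(stats::runif(n, log(multiplier[1]), log(multiplier[2])))
  thg <- stats::rlnorm(n, log(background_median), log(background_gsd)) * mult
  law <- mehg_power_law(site_class)
  mehg <- law$a * thg^law$b * stats::rlnorm(n, 0, log(noise_gsd))
  tibble::tibble(
    record_id = sprintf("SITE%03d_%s", rep(seq_len(n), 2L),
                        rep(c("THg", "MeHg"), each = n)),
    country = country,
    lat = lat + rep(stats::runif(n, -0.5, 0.5), 2L)[seq_len(2L * n)],
    lon = lon + rep(stats::runif(n, -0.5, 0.5), 2L)[seq_len(2L * n)],
    site_class = site_class, organ = "grain",
    species = rep(c("THg", "MeHg"), each = n),
    median_ng_g = c(thg, mehg), gsd = 1.5,
    n = sample(5:30, 2L * n, replace = TRUE))
}

#' Write and read a synthetic world as the standard file set
#'
#' `write_world()` writes every pipeline input as CSV plus
#' `ground_truth.json` (latent values, never read by the analysis) and
#' `world_config.json`. `read_world()` loads the file set back through the
#' validating readers.
#'
#' @param world A `ricehg_world`.
#' @param dir Directory (created if needed).
#' @return `read_world()` returns a `ricehg_world` (truth included when
#'   `ground_truth.json` is present).
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "ricehg_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_balance_sheets(world$sheets, p("balance_sheets.csv"))
  if (!is.null(world$trade)) write_trade_matrix(world$trade, p("trade_matrix.csv"))
  utils::write.csv(world$records, p("concentrations.csv"), row.names = FALSE)
  utils::write.csv(world$demographics, p("demographics.csv"), row.names = FALSE)
  utils::write.csv(world$baselines, p("baselines.csv"), row.names = FALSE)
  utils::write.csv(world$fates, p("fates.csv"), row.names = FALSE)
  utils::write.csv(world$enrichment, p("enrichment.csv"), row.names = FALSE)
  utils::write.csv(world$residues, p("residues.csv"), row.names = FALSE)
  utils::write.csv(world$countries, p("countries.csv"), row.names = FALSE)
  jsonlite::write_json(world$truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(world$config), p("world_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg_raw <- jsonlite::read_json(p("world_config.json"), simplifyVector = TRUE)
  cfg <- do.call(world_config, cfg_raw[names(cfg_raw) %in%
                                         names(formals(world_config))])
  truth <- NULL
  if (file.exists(p("ground_truth.json"))) {
    tr <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
    truth <- list(
      concentrations = tibble::as_tibble(tr$concentrations),
      trade_embodied_share_mehg = tr$trade_embodied_share_mehg,
      global_grain_thg_kg = tr$global_grain_thg_kg,
      global_grain_mehg_kg = tr$global_grain_mehg_kg)
  }
  structure(list(
    config = cfg,
    countries = tibble::as_tibble(utils::read.csv(p("countries.csv"))),
    records = read_concentrations(p("concentrations.csv")),
    sheets = read_balance_sheets(p("balance_sheets.csv")),
    trade = if (file.exists(p("trade_matrix.csv")))
      read_trade_matrix(p("trade_matrix.csv")) else NULL,
    demographics = read_demographics(p("demographics.csv")),
    baselines = read_baselines(p("baselines.csv")),
    fates = read_fates(p("fates.csv")),
    enrichment = read_enrichment(p("enrichment.csv")),
    residues = read_residues(p("residues.csv")),
    truth = truth), class = "ricehg_world")
}
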