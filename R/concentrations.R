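# Grain mercury concentration modelling: record validation, log-normal
# median sampling, THg <-> MeHg power-law imputation, and per-country
# concentration surfaces.

SITE_CLASSES <- c("background", "gold_mining", "hg_mining", "smelting",
                  "chloralkali", "other_industrial")
ORGANS <- c("grain", "stem", "leaf", "residue_bulk")
HG_SPECIES <- c("THg", "MeHg")

# Geometric SD implied by the default 65% relative uncertainty: a log-normal
# whose central 95% interval is median * [1/1.65, 1.65].
#' Default geometric standard deviation for records without a reported SD
#'
#' Records lacking a dispersion estimate are assigned a 65% relative
#' uncertainty, mapped to a log-normal whose 95% interval is
#' `median * c(1/1.65, 1.65)`, i.e. `gsd = exp(log(1.65)/qnorm(0.975))`.
#'
#' @return The default geometric standard deviation (about 1.29).
#' @export
default_gsd <- function() {
  exp(log(1.65) / stats::qnorm(0.975))
}

#' Power-law coefficients relating MeHg to THg in rice grain
#'
#' The fitted relation `MeHg = a * THg^b` (both in ng/g) used to impute the
#' missing mercury species. Background (non-contaminated) sites use
#' `a = 0.80, b = 0.65`; every contaminated site class uses
#' `a = 0.74, b = 0.67`. Standard errors of the fits are carried for Monte
#' Carlo perturbation.
#'
#' @param site_class One of the site classes; anything other than
#'   `"background"` selects the contaminated-site fit.
#' @return List with `a`, `b`, `a_se`, `b_se`, `r2`.
#' @export
mehg_power_law <- function(site_class = "background") {
  stopifnot(site_class %in% SITE_CLASSES)
  if (site_class == "background") {
    list(a = 0.80, b = 0.65, a_se = 1.1, b_se = 0.072, r2 = 0.46)
  } else {
    list(a = 0.74, b = 0.67, a_se = 1.4, b_se = 0.091, r2 = 0.61)
  }
}

#' Validate and flag a table of concentration records
#'
#' Applies the inclusion rules to a table of literature-style measurement
#' summaries: medians must be positive, the geometric SD (when present)
#' must exceed 1, records with fewer than 3 samples are flagged excluded,
#' and records collected before the cutoff year (when a `year` column is
#' present) are excluded.
#'
#' @param records Data frame with columns `record_id`, `country`, `lat`,
#'   `lon`, `site_class`, `organ`, `species`, `median_ng_g`, `gsd`, `n`
#'   (and optionally `year`).
#' @param min_n Minimum sample count for inclusion (default 3).
#' @param cutoff_year Records before this year are excluded (default 2000);
#'   `NULL` disables the cutoff.
#' @return The records tibble with a logical `included` column.
#' @export
validate_records <- function(records, min_n = 3L, cutoff_year = 2000L) {
  req <- c("record_id", "country", "lat", "lon", "site_class", "organ",
           "species", "median_ng_g", "gsd", "n")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) {
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (any(!records$site_class %in% SITE_CLASSES)) {
    stop("unknown site_class; valid classes: ",
         paste(SITE_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (any(!records$organ %in% ORGANS)) {
    stop("unknown organ; valid organs: ", paste(ORGANS, collapse = ", "),
         call. = FALSE)
  }
  if (any(!records$species %in% HG_SPECIES)) {
    stop("species must be THg or MeHg", call. = FALSE)
  }
  if (any(records$median_ng_g <= 0)) {
    stop("record medians must be positive", call. = FALSE)
  }
  if (any(!is.na(records$gsd) & records$gsd <= 1)) {
    stop("gsd must exceed 1 when present", call. = FALSE)
  }
  records$included <- records$n >= min_n
  if (!is.null(cutoff_year) && "year" %in% names(records)) {
    records$included <- records$included &
      (is.na(records$year) | records$year >= cutoff_year)
  }
  records
}

#' Sample a plausible median from one concentration record
#'
#' Draws from a log-normal centred on the record's median with the record's
#' geometric SD; records without a reported dispersion use the 65% default
#' ([default_gsd()]). With `gsd = 1` every draw equals the median.
#'
#' @param median_ng_g Record median, ng/g (> 0).
#' @param gsd Geometric SD (>= 1) or `NA` for the default.
#' @param n Number of draws.
#' @return Positive numeric vector of length `n`, ng/g.
#' @export
sample_median <- function(median_ng_g, gsd = NA_real_, n = 1L) {
  if (!is.numeric(median_ng_g) || median_ng_g <= 0) {
    stop("record median must be positive", call. = FALSE)
  }
  if (is.na(gsd)) gsd <- default_gsd()
  stopifnot(gsd >= 1)
  stats::rlnorm(n, meanlog = log(median_ng_g), sdlog = log(gsd))
}

#' Impute grain MeHg from THg (and the inverse)
#'
#' Applies the fitted power law `MeHg = a * THg^b`, with coefficients
#' selected by site class (see [mehg_power_law()]). The relation passes
#' through the origin, so `thg = 0` maps to 0. The inverse direction
#' (`impute_thg_from_mehg()`) inverts the same law analytically,
#' `THg = (MeHg/a)^(1/b)`, for the rare records reporting MeHg only.
#'
#' @param thg,mehg Concentration in ng/g (>= 0); vectorised.
#' @param site_class Site class selecting the coefficient set.
#' @param coef Optional coefficient list overriding [mehg_power_law()]
#'   (used by the Monte Carlo to perturb `a` and `b`).
#' @return Imputed concentration in ng/g.
#' @examples
#' impute_mehg_from_thg(1, "background")   # 0.80
#' impute_mehg_from_thg(1, "gold_mining")  # 0.74
#' @export
impute_mehg_from_thg <- function(thg, site_class = "background", coef = NULL) {
  if (any(thg < 0)) stop("THg must be nonnegative", call. = FALSE)
  if (is.null(coef)) coef <- mehg_power_law(site_class)
  ifelse(thg == 0, 0, coef$a * thg^coef$b)
}

#' @rdname impute_mehg_from_thg
#' @export
impute_thg_from_mehg <- function(mehg, site_class = "background", coef = NULL) {
  if (any(mehg < 0)) stop("MeHg must be nonnegative", call. = FALSE)
  if (is.null(coef)) coef <- mehg_power_law(site_class)
  ifelse(mehg == 0, 0, (mehg / coef$a)^(1 / coef$b))
}

#' Fit a power law y = a * x^b by log-log least squares
#'
#' Ordinary least squares of `log(y)` on `log(x)`, back-transformed. The
#' multiplicative coefficient `a` is `exp(intercept)`; its standard error
#' is reported on the natural scale by the delta method
#' (`a_se = a * se(intercept)`). The p-value is the t-test on the slope.
#'
#' @param x,y Positive numeric vectors of equal length (>= 3 pairs).
#' @return List with `a`, `b`, `a_se`, `b_se`, `r2`, `p`, `n`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("all values must be positive for a log-log fit", call. = FALSE)
  }
  if (stats::var(log(x)) == 0) {
    stop("zero variance in the regressor", call. = FALSE)
  }
  fit <- stats::lm(log(y) ~ log(x))
  sm <- summary(fit)
  co <- sm$coefficients
  a <- exp(co[1, 1])
  list(
    a = a,
    b = co[2, 1],
    a_se = a * co[1, 2],
    b_se = co[2, 2],
    r2 = sm$r.squared,
    p = co[2, 4],
    n = length(x)
  )
}

# Weighted median: smallest value whose cumulative weight reaches half the
# total. Used to pool multiple record medians within a country.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Pool grain records into one national concentration per species
#'
#' For each (country, species), takes the median of record medians weighted
#' by sample count `n`. Only included, background, grain records enter
#' national surfaces; contaminated-site records are excluded (that rice is
#' treated as locally consumed and never enters national supply).
#'
#' @param records Validated records (see [validate_records()]).
#' @param organ Organ to pool (default `"grain"`).
#' @return Tibble with `country`, `species`, `median_ng_g`, `gsd`,
#'   `n_records`. `gsd` is the n-weighted median of record gsds (default
#'   gsd substituted where absent).
#' @export
pool_country_records <- function(records, organ = "grain") {
  records <- validate_records(records)
  keep <- records$included & records$site_class == "background" &
    records$organ == organ
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L) {
    return(tibble::tibble(country = character(), species = character(),
                          median_ng_g = numeric(), gsd = numeric(),
                          n_records = integer()))
  }
  r$gsd[is.na(r$gsd)] <- default_gsd()
  grp <- split(r, list(r$country, r$species), drop = TRUE)
  out <- lapply(grp, function(g) {
    tibble::tibble(
      country = g$country[1],
      species = g$species[1],
      median_ng_g = weighted_median(g$median_ng_g, g$n),
      gsd = weighted_median(g$gsd, g$n),
      n_records = nrow(g)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$country, .data$species)
}

#' National grain THg and MeHg concentrations for every country
#'
#' Builds the per-country grain concentration table the material-flow
#' ledger consumes. Measured countries use their own pooled background
#' grain records; a country with only one species measured gets the other
#' imputed through the power law (forward THg to MeHg, or the analytic
#' inverse); countries with no records get ordinary-kriging predictions on
#' the log scale from the measured countries.
#'
#' @param records Concentration records table.
#' @param targets Tibble `country`, `lat`, `lon` of the countries needing a
#'   value (typically all countries in the world, with centroids).
#' @param spec Variogram specification from [variogram_spec()], or `NULL`
#'   to fit one from the measured values ([fit_variogram()]).
#' @return Tibble `country`, `thg_ng_g`, `mehg_ng_g`, `source`
#'   (`"measured"`, `"imputed"`, or `"kriged"` per species, collapsed as
#'   `"thg:mehg"`), plus `thg_gsd`, `mehg_gsd` dispersions for Monte Carlo.
#' @export
country_grain_concentration <- function(records, targets, spec = NULL) {
  stopifnot(all(c("country", "lat", "lon") %in% names(targets)))
  pooled <- pool_country_records(records, organ = "grain")
  if (nrow(pooled) == 0L) stop("no usable grain records", call. = FALSE)

  wide <- function(sp) {
    p <- pooled[pooled$species == sp, ]
    stats::setNames(p$median_ng_g, p$country)
  }
  gsd_wide <- function(sp) {
    p <- pooled[pooled$species == sp, ]
    stats::setNames(p$gsd, p$country)
  }
  thg <- wide("THg"); mehg <- wide("MeHg")
  thg_gsd <- gsd_wide("THg"); mehg_gsd <- gsd_wide("MeHg")

  out <- tibble::tibble(country = targets$country, lat = targets$lat,
                        lon = targets$lon)
  out$thg_ng_g <- unname(thg[out$country])
  out$mehg_ng_g <- unname(mehg[out$country])
  out$thg_src <- ifelse(is.na(out$thg_ng_g), NA_character_, "measured")
  out$mehg_src <- ifelse(is.na(out$mehg_ng_g), NA_character_, "measured")

  # Cross-species imputation where one species is measured.
  i <- is.na(out$thg_ng_g) & !is.na(out$mehg_ng_g)
  out$thg_ng_g[i] <- impute_thg_from_mehg(out$mehg_ng_g[i])
  out$thg_src[i] <- "imputed"
  i <- is.na(out$mehg_ng_g) & !is.na(out$thg_ng_g) & out$thg_src == "measured"
  out$mehg_ng_g[i] <- impute_mehg_from_thg(out$thg_ng_g[i])
  out$mehg_src[i] <- "imputed"

  # Kriging for countries with neither species measured.
  for (sp in c("thg", "mehg")) {
    col <- paste0(sp, "_ng_g"); src <- paste0(sp, "_src")
    need <- is.na(out[[col]])
    if (!any(need)) next
    have <- !is.na(out[[col]])
    if (sum(have) == 1L) {
      # single datum: ordinary kriging collapses to that value
      out[[col]][need] <- out[[col]][have]
    } else {
      samples <- tibble::tibble(lat = out$lat[have], lon = out$lon[have],
                                value = log(out[[col]][have]))
      vs <- spec
      if (is.null(vs)) vs <- fit_variogram(samples)
      kr <- krige_country_surface(samples,
                                  targets = out[need, c("country", "lat", "lon")],
                                  spec = vs)
      out[[col]][need] <- exp(kr$prediction)
    }
    out[[src]][need] <- "kriged"
  }

  dflt <- default_gsd()
  out$thg_gsd <- ifelse(out$country %in% names(thg_gsd),
                        unname(thg_gsd[out$country]), dflt)
  out$mehg_gsd <- ifelse(out$country %in% names(mehg_gsd),
                         unname(mehg_gsd[out$country]), dflt)
  out$source <- paste(out$thg_src, out$mehg_src, sep = ":")
  out[, c("country", "lat", "lon", "thg_ng_g", "mehg_ng_g",
          "thg_gsd", "mehg_gsd", "source")]
}
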