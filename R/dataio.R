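# Tabular input/output and run configuration. CSV is the single tabular
# interchange format; JSON holds configuration and envelopes. Units:
# masses Mg/yr (milled equivalent), concentrations ng/g, fluxes kg/yr,
# PWI ug kg-1 week-1. Country identifiers are opaque keys.

#' Run configuration
#'
#' Bundles everything a reproducible pipeline run needs: Monte Carlo
#' repetitions and seed, the analysis year, the envelope probabilities, and
#' input paths.
#'
#' @param n_draws Monte Carlo repetitions (>= 1, default 10000).
#' @param seed Integer seed.
#' @param year Calendar year of the analysis.
#' @param iqr_bounds Envelope probabilities, strictly ordered; default
#'   `c(0.25, 0.75)`.
#' @param paths Named list of input-table paths (may be empty when the
#'   world is passed in memory).
#' @param coefficient_set Identifier of the health-coefficient set.
#' @return Object of class `ricehg_config`.
#' @export
run_config <- function(n_draws = 10000L, seed = 1L, year = 2013L,
                       iqr_bounds = c(0.25, 0.75), paths = list(),
                       coefficient_set = "default") {
  stopifnot(n_draws >= 1L, length(iqr_bounds) == 2L,
            iqr_bounds[1] < iqr_bounds[2],
            iqr_bounds[1] > 0, iqr_bounds[2] < 1)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 year = as.integer(year), iqr_bounds = iqr_bounds,
                 units = list(mass = "Mg/yr", concentration = "ng/g",
                              flux = "kg/yr", pwi = "ug kg-1 week-1"),
                 paths = paths, coefficient_set = coefficient_set),
            class = "ricehg_config")
}

#' Write and read a run configuration as JSON
#' @param config A `ricehg_config`.
#' @param path JSON path.
#' @return `read_config()` returns the `ricehg_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ricehg_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(n_draws = x$n_draws, seed = x$seed, year = x$year,
             iqr_bounds = as.numeric(x$iqr_bounds),
             paths = as.list(x$paths), coefficient_set = x$coefficient_set)
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(basename(path), " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read commodity balance sheets
#'
#' Long CSV with columns `country`, `year`, `term`, `quantity_Mg`, one row
#' per reported term. Terms must come from [balance_terms()]; every term
#' other than stock variation must be nonnegative. The result is one wide
#' row per (country, year) with all ten term columns; terms absent from the
#' file default to zero with one warning listing the affected sheets.
#'
#' @param path CSV path.
#' @return Wide tibble `country`, `year`, plus the ten term columns (Mg/yr).
#' @export
read_balance_sheets <- function(path) {
  df <- read_csv_strict(path, c("country", "year", "term", "quantity_Mg"))
  if (nrow(df) == 0L) {
    out <- tibble::as_tibble(c(list(country = character(), year = integer()),
      stats::setNames(rep(list(numeric()), 10L), balance_terms())))
    return(out)
  }
  bad <- setdiff(unique(df$term), balance_terms())
  if (length(bad) > 0L) {
    stop("unknown balance term(s) ", paste(sQuote(bad), collapse = ", "),
         "; valid terms: ", paste(balance_terms(), collapse = ", "),
         call. = FALSE)
  }
  neg <- df$quantity_Mg < 0 & df$term != "stock_variation"
  if (any(neg)) {
    stop("negative quantity for term(s) other than stock_variation: ",
         paste(unique(df$term[neg]), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("country", "year", "term")])
  if (any(dup)) stop("duplicate (country, year, term) rows", call. = FALSE)

  keys <- unique(df[, c("country", "year")])
  wide <- keys
  for (tm in balance_terms()) {
    sub <- df[df$term == tm, ]
    idx <- match(paste(keys$country, keys$year),
                 paste(sub$country, sub$year))
    wide[[tm]] <- ifelse(is.na(idx), NA_real_, sub$quantity_Mg[idx])
  }
  n_missing <- sum(is.na(as.matrix(wide[, balance_terms()])))
  if (n_missing > 0L) {
    warning(n_missing, " missing term value(s) defaulted to zero")
    for (tm in balance_terms()) wide[[tm]][is.na(wide[[tm]])] <- 0
  }
  tibble::as_tibble(wide)
}

#' Write balance sheets back to long CSV
#' @param sheets Wide balance-sheet tibble.
#' @param path Output CSV path.
#' @export
write_balance_sheets <- function(sheets, path) {
  long <- do.call(rbind, lapply(balance_terms(), function(tm) {
    data.frame(country = sheets$country, year = sheets$year, term = tm,
               quantity_Mg = sheets[[tm]])
  }))
  long <- long[order(long$country, long$year, long$term), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read the bilateral trade matrix
#'
#' Long CSV `reporter`, `partner`, `quantity_Mg` (Mg/yr of milled rice from
#' reporter to partner). Self-trade rows, negative quantities and duplicate
#' (reporter, partner) pairs are errors.
#'
#' @param path CSV path.
#' @return Tibble `reporter`, `partner`, `quantity_Mg`.
#' @export
read_trade_matrix <- function(path) {
  df <- read_csv_strict(path, c("reporter", "partner", "quantity_Mg"))
  if (nrow(df) == 0L) return(df)
  if (any(df$reporter == df$partner)) {
    stop("self-trade rows (reporter == partner) are not allowed", call. = FALSE)
  }
  if (any(df$quantity_Mg < 0)) {
    stop("negative trade quantities are not allowed", call. = FALSE)
  }
  if (any(duplicated(df[, c("reporter", "partner")]))) {
    stop("duplicate (reporter, partner) rows", call. = FALSE)
  }
  df
}

#' Write the trade matrix
#' @param trade Tibble `reporter`, `partner`, `quantity_Mg`.
#' @param path Output CSV path.
#' @export
write_trade_matrix <- function(trade, path) {
  utils::write.csv(trade[order(trade$reporter, trade$partner), ],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read concentration records
#'
#' CSV with columns `record_id`, `country`, `lat`, `lon`, `site_class`,
#' `organ`, `species`, `median_ng_g`, `gsd`, `n` (and optionally `year`),
#' validated and flagged by [validate_records()].
#'
#' @param path CSV path.
#' @param ... Passed to [validate_records()].
#' @return Validated records tibble with an `included` flag.
#' @export
read_concentrations <- function(path, ...) {
  df <- read_csv_strict(path, c("record_id", "country", "lat", "lon",
                                "site_class", "organ", "species",
                                "median_ng_g", "gsd", "n"))
  validate_records(df, ...)
}

#' Read demographics and health baselines
#'
#' `read_demographics()`: CSV `country`, `continent`, `population`,
#' `body_weight_kg` (body weight may be blank, in which case the
#' continental default from [continent_body_weights()] is filled in).
#' `read_baselines()`: CSV `country`, `fatal_heart_attacks_ge30`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_demographics <- function(path) {
  df <- read_csv_strict(path, c("country", "continent", "population"))
  if (!"body_weight_kg" %in% names(df)) df$body_weight_kg <- NA_real_
  bw <- continent_body_weights()
  fill <- is.na(df$body_weight_kg)
  df$body_weight_kg[fill] <- unname(bw[df$continent[fill]])
  if (any(is.na(df$body_weight_kg))) {
    stop("unknown continent(s) without body weight: ",
         paste(unique(df$continent[is.na(df$body_weight_kg)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$population <= 0)) stop("population must be positive", call. = FALSE)
  df
}

#' @rdname read_demographics
#' @export
read_baselines <- function(path) {
  df <- read_csv_strict(path, c("country", "fatal_heart_attacks_ge30"))
  if (any(df$fatal_heart_attacks_ge30 < 0)) {
    stop("baseline deaths must be >= 0", call. = FALSE)
  }
  df
}

#' Read auxiliary tables: fate fractions, enrichment factors, residues
#'
#' `read_fates()`: CSV `country`, `fate`, `fraction`, `scenario`.
#' `read_enrichment()`: CSV `region`, `year`, `ef`.
#' `read_residues()`: CSV `country`, `residue_n_Mg` (total nitrogen held in
#' rice residues, the basis of the residue-mass estimate).
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_fates <- function(path) {
  df <- read_csv_strict(path, c("country", "fate", "fraction"))
  bad <- setdiff(unique(df$fate), fate_names())
  if (length(bad) > 0L) {
    stop("unknown fate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$fraction < 0 | df$fraction > 1)) {
    stop("fate fractions must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' @rdname read_fates
#' @export
read_enrichment <- function(path) {
  df <- read_csv_strict(path, c("region", "year", "ef"))
  if (any(df$ef <= 0)) stop("enrichment factors must be positive", call. = FALSE)
  df
}

#' @rdname read_fates
#' @export
read_residues <- function(path) {
  df <- read_csv_strict(path, c("country", "residue_n_Mg"))
  if (any(df$residue_n_Mg < 0)) stop("residue nitrogen must be >= 0", call. = FALSE)
  df
}
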