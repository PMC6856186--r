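# Concentration-weighted mercury flux ledgers over commodity balance
# sheets and the bilateral trade matrix; trade-attribution statistics.

#' The ten commodity-balance terms
#'
#' Source-side terms are production, import and stock variation (signed:
#' positive stock variation is a drawdown adding to supply); sink-side
#' terms are export, feed, seed, processing, other uses, food and losses.
#' Mass balance requires
#' `production - export + stock_variation + import =
#'  feed + seed + processing + other_uses + food + losses`.
#'
#' @return Character vector of the ten term names.
#' @export
balance_terms <- function() {
  c("production", "import", "stock_variation", "export",
    "feed", "seed", "processing", "other_uses", "food", "losses")
}

SINK_TERMS <- c("feed", "seed", "processing", "other_uses", "food", "losses")

#' Check commodity-balance closure of mass sheets
#'
#' @param sheets Wide balance-sheet tibble (one row per country-year, one
#'   column per term; see [read_balance_sheets()]).
#' @param tol Relative tolerance on `|sources - sinks|` against total
#'   source mass.
#' @return Tibble `country`, `year`, `residual_Mg`, `pass`.
#' @export
check_sheet_closure <- function(sheets, tol = 1e-9) {
  src <- sheets$production - sheets$export + sheets$stock_variation +
    sheets$import
  snk <- rowSums(as.matrix(sheets[, SINK_TERMS]))
  scale <- pmax(abs(sheets$production) + abs(sheets$import) +
                  abs(sheets$stock_variation), 1)
  tibble::tibble(country = sheets$country, year = sheets$year,
                 residual_Mg = src - snk,
                 pass = abs(src - snk) <= tol * scale)
}

#' Mercury flux carried by a rice mass
#'
#' Unit bridge: `Mg/yr * ng/g -> kg/yr` is a factor `1e-6`
#' (1 Mg = 1e6 g; 1 ng/g of 1e6 g is 1e-3 g = 1e-6 kg).
#'
#' @param mass Rice mass, Mg/yr (>= 0).
#' @param conc Mercury concentration, ng/g (>= 0).
#' @return Mercury flux, kg/yr.
#' @examples
#' hg_flux(1, 100)  # 1e-4 kg
#' @export
hg_flux <- function(mass, conc) {
  if (any(mass < 0)) stop("mass must be >= 0 (stock variation is handled by its signed wrapper)", call. = FALSE)
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  mass * conc * 1e-6
}

# Signed variant for stock variation only.
hg_flux_signed <- function(mass, conc) {
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  mass * conc * 1e-6
}

reconcile_trade <- function(trade, sheets) {
  if (is.null(trade) || nrow(trade) == 0L) return(trade)
  exp_term <- stats::setNames(sheets$export, sheets$country)
  for (rep_c in unique(trade$reporter)) {
    rows <- trade$reporter == rep_c
    rs <- sum(trade$quantity_Mg[rows])
    target <- exp_term[[rep_c]]
    if (rs > 0 && abs(rs - target) > 1e-9 * max(rs, target, 1)) {
      message("rescaling trade rows of ", rep_c, " from ",
              format(rs), " to the export term ", format(target), " Mg")
      trade$quantity_Mg[rows] <- trade$quantity_Mg[rows] * target / rs
    }
  }
  trade
}

#' Build the mercury flux ledger for one year
#'
#' Converts a set of closed balance sheets into THg and MeHg flux ledgers.
#' Domestic source terms (production, stock variation) and the export term
#' are valued at the producing country's grain concentration; each
#' bilateral import flow is valued at the exporting partner's
#' concentration. Domestic sinks draw from a pooled supply (domestic
#' production net of exports plus imports), so every sink term is valued at
#' the mass-weighted pool concentration, and the food term is split into
#' domestic-origin and import-origin shares in proportion to the pool's
#' mercury provenance.
#'
#' @param sheets Wide balance-sheet tibble for one year.
#' @param conc Tibble `country`, `thg_ng_g`, `mehg_ng_g` covering every
#'   country in `sheets` (see [country_grain_concentration()]).
#' @param trade Long trade matrix `reporter`, `partner`, `quantity_Mg`, or
#'   `NULL` for an autarkic world. Rows whose reporter sum mismatches the
#'   export term are proportionally rescaled (with a message). Trade rows
#'   naming countries absent from the sheets are an error.
#' @return Object of class `ricehg_ledger`: a list with `fluxes` (long
#'   tibble `country`, `year`, `species`, `term`, `flux_kg`), `food`
#'   (per-country food split: `food_kg`, `food_domestic_kg`,
#'   `food_import_kg`, `pool_conc_ng_g`), and `bilateral` (`exporter`,
#'   `importer`, `species`, `flux_kg`).
#' @export
build_ledger <- function(sheets, conc, trade = NULL) {
  stopifnot(all(c("country", "thg_ng_g", "mehg_ng_g") %in% names(conc)))
  missing_conc <- setdiff(sheets$country, conc$country)
  if (length(missing_conc) > 0L) {
    stop("no concentration for: ", paste(missing_conc, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(trade) && nrow(trade) > 0L) {
    unknown <- setdiff(unique(c(trade$reporter, trade$partner)), sheets$country)
    if (length(unknown) > 0L) {
      stop("trade rows reference unknown countries: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    trade <- reconcile_trade(trade, sheets)
  }

  fluxes <- list(); food <- list(); bilateral <- list()
  for (sp in c("THg", "MeHg")) {
    c_own <- stats::setNames(
      if (sp == "THg") conc$thg_ng_g else conc$mehg_ng_g, conc$country)
    cs <- unname(c_own[sheets$country])

    imp_hg <- rep(0, nrow(sheets))
    imp_mass <- rep(0, nrow(sheets))
    if (!is.null(trade) && nrow(trade) > 0L) {
      bi_flux <- hg_flux(trade$quantity_Mg, unname(c_own[trade$reporter]))
      agg <- rowsum(cbind(bi_flux, trade$quantity_Mg), trade$partner)
      idx <- match(sheets$country, rownames(agg))
      imp_hg <- ifelse(is.na(idx), 0, agg[idx, 1])
      imp_mass <- ifelse(is.na(idx), 0, agg[idx, 2])
      bilateral[[sp]] <- tibble::tibble(
        exporter = trade$reporter, importer = trade$partner,
        species = sp, flux_kg = bi_flux)
    } else {
      # no matrix: value the sheet's import term at the country's own
      # concentration (degenerate, but keeps the ledger defined)
      imp_mass <- sheets$import
      imp_hg <- hg_flux(sheets$import, cs)
    }

    dom_mass <- sheets$production - sheets$export + sheets$stock_variation
    pool_mass <- dom_mass + imp_mass
    pool_hg <- hg_flux_signed(dom_mass, cs) + imp_hg
    pool_conc <- ifelse(pool_mass > 0, pool_hg / pool_mass / 1e-6, 0)

    term_flux <- tibble::tibble(
      country = rep(sheets$country, times = 10L),
      year = rep(sheets$year, times = 10L),
      species = sp,
      term = rep(balance_terms(), each = nrow(sheets)),
      flux_kg = c(
        hg_flux(sheets$production, cs),
        imp_hg,
        hg_flux_signed(sheets$stock_variation, cs),
        hg_flux(sheets$export, cs),
        unlist(lapply(SINK_TERMS, function(tm) {
          hg_flux(sheets[[tm]], pool_conc)
        }), use.names = FALSE)
      )
    )
    fluxes[[sp]] <- term_flux

    food_hg <- hg_flux(sheets$food, pool_conc)
    imp_share <- ifelse(pool_hg > 0, imp_hg / pool_hg, 0)
    food[[sp]] <- tibble::tibble(
      country = sheets$country, year = sheets$year, species = sp,
      food_kg = food_hg,
      food_import_kg = food_hg * imp_share,
      food_domestic_kg = food_hg * (1 - imp_share),
      pool_conc_ng_g = pool_conc
    )
  }
  structure(
    list(fluxes = dplyr::bind_rows(fluxes),
         food = dplyr::bind_rows(food),
         bilateral = if (length(bilateral) > 0L) dplyr::bind_rows(bilateral)
                     else tibble::tibble(exporter = character(),
                                         importer = character(),
                                         species = character(),
                                         flux_kg = numeric())),
    class = "ricehg_ledger"
  )
}

#' Mass-balance residuals of a flux ledger
#'
#' Signed residual (sources minus sinks, kg/yr) per country and species,
#' and a pass flag at the given relative tolerance. A ledger built from a
#' closed sheet with a consistent trade matrix closes to numerical
#' precision.
#'
#' @param ledger A `ricehg_ledger`.
#' @param tol Relative tolerance against total source flux.
#' @return Tibble `country`, `species`, `residual_kg`, `pass`.
#' @export
check_balance <- function(ledger, tol = 1e-9) {
  f <- ledger$fluxes
  wide <- split(f, list(f$country, f$species), drop = TRUE)
  out <- lapply(wide, function(g) {
    fx <- stats::setNames(g$flux_kg, g$term)
    src <- fx[["production"]] - fx[["export"]] + fx[["stock_variation"]] +
      fx[["import"]]
    snk <- sum(fx[SINK_TERMS])
    scale <- max(abs(fx[["production"]]) + abs(fx[["import"]]) +
                   abs(fx[["stock_variation"]]), 1e-300)
    tibble::tibble(country = g$country[1], species = g$species[1],
                   residual_kg = src - snk,
                   pass = abs(src - snk) <= tol * scale)
  })
  dplyr::bind_rows(out)
}

#' Share of food-supply mercury embodied in international trade
#'
#' Fraction of the mercury reaching national food supplies that originated
#' abroad: `sum(import-origin food Hg) / sum(total food Hg)`, globally and
#' (when a region map is supplied) per region.
#'
#' @param ledger A `ricehg_ledger`.
#' @param species `"MeHg"` (default) or `"THg"`.
#' @param regions Optional tibble `country`, `region` for a per-region
#'   breakdown.
#' @return List with `global` (scalar in `[0, 1]`; 0 with a warning when no
#'   mercury reaches food at all) and `by_region` (tibble or `NULL`).
#' @export
trade_embodied_share <- function(ledger, species = "MeHg", regions = NULL) {
  fd <- ledger$food[ledger$food$species == species, ]
  tot <- sum(fd$food_kg)
  if (tot == 0) {
    warning("no mercury in any food supply; trade-embodied share defined as 0")
    g <- 0
  } else {
    g <- sum(fd$food_import_kg) / tot
  }
  by_region <- NULL
  if (!is.null(regions)) {
    fd2 <- dplyr::left_join(fd, regions, by = "country")
    by_region <- dplyr::summarise(
      dplyr::group_by(fd2, .data$region),
      share = ifelse(sum(.data$food_kg) == 0, 0,
                     sum(.data$food_import_kg) / sum(.data$food_kg)),
      .groups = "drop")
  }
  list(global = g, by_region = by_region)
}

#' Trade impact on food-supply mercury vs an autarky counterfactual
#'
#' For each country, compares the actual mercury in the food supply with a
#' counterfactual in which the same food mass is valued at the domestic
#' concentration: the country's own grain concentration when it produces
#' rice, otherwise its region's production-weighted mean concentration.
#' Countries with neither domestic production nor a regional fallback are
#' flagged undefined (`NA` delta).
#'
#' @param ledger A `ricehg_ledger`.
#' @param sheets The balance sheets the ledger was built from.
#' @param conc Concentration table used for the ledger.
#' @param species `"MeHg"` (default) or `"THg"`.
#' @param regions Optional tibble `country`, `region` enabling the regional
#'   fallback.
#' @return Tibble `country`, `food_kg`, `counterfactual_kg`, `delta`
#'   (fractional change, e.g. `1` = +100%), `defined`.
#' @export
trade_delta <- function(ledger, sheets, conc, species = "MeHg",
                        regions = NULL) {
  fd <- ledger$food[ledger$food$species == species, ]
  col <- if (species == "THg") "thg_ng_g" else "mehg_ng_g"
  c_own <- stats::setNames(conc[[col]], conc$country)
  prod <- stats::setNames(sheets$production, sheets$country)

  region_mean <- NULL
  if (!is.null(regions)) {
    df <- dplyr::left_join(regions, tibble::tibble(
      country = names(prod), production = unname(prod),
      conc = unname(c_own[names(prod)])), by = "country")
    df <- df[!is.na(df$production) & df$production > 0, ]
    region_mean <- dplyr::summarise(
      dplyr::group_by(df, .data$region),
      conc = sum(.data$production * .data$conc) / sum(.data$production),
      .groups = "drop")
  }

  cf_conc <- vapply(fd$country, function(cc) {
    if (!is.na(prod[cc]) && prod[cc] > 0) return(unname(c_own[cc]))
    if (!is.null(region_mean) && !is.null(regions)) {
      reg <- regions$region[regions$country == cc]
      if (length(reg) == 1L) {
        m <- region_mean$conc[region_mean$region == reg]
        if (length(m) == 1L) return(m)
      }
    }
    NA_real_
  }, numeric(1))

  cf_conc <- unname(cf_conc)
  food_mass <- stats::setNames(sheets$food, sheets$country)[fd$country]
  cf_kg <- hg_flux(unname(food_mass), ifelse(is.na(cf_conc), 0, cf_conc))
  cf_kg[is.na(cf_conc)] <- NA_real_
  delta <- ifelse(is.na(cf_kg) | cf_kg == 0, NA_real_,
                  fd$food_kg / cf_kg - 1)
  tibble::tibble(country = fd$country, food_kg = fd$food_kg,
                 counterfactual_kg = cf_kg, delta = delta,
                 defined = !is.na(delta))
}
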