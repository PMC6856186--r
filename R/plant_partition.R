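# Grain-to-organ concentration relations, residue mass from nitrogen
# content, enrichment-factor time scaling, and other-crop residue THg.

#' Fitted relations between grain and other rice-organ concentrations
#'
#' The eight fitted relations converting grain concentrations (ng/g) to
#' stem, leaf and bulk-residue concentrations, for THg and MeHg. Two are
#' linear (`a * x + b`): residue THg from grain THg and leaf THg from grain
#' THg; the rest are power laws (`a * x^b`). Coefficient standard errors
#' are carried so the Monte Carlo can perturb them.
#'
#' @return Tibble with `relation_id`, `form`, `a`, `a_se`, `b`, `b_se`, `r2`.
#' @export
organ_relations <- function() {
  tibble::tribble(
    ~relation_id,           ~form,    ~a,   ~a_se, ~b,   ~b_se,  ~r2,
    "residues_thg",         "linear", 7.5,  0.34,  34,   38,     0.84,
    "stem_thg",             "power",  4.3,  1.3,   0.92, 0.063,  0.83,
    "leaf_thg_from_grain",  "linear", 20,   1.0,   18,   160,    0.91,
    "leaf_thg_from_stem",   "power",  2.1,  1.4,   1.2,  0.067,  0.88,
    "residues_mehg",        "power",  0.27, 1.3,   1.1,  0.10,   0.80,
    "stem_mehg",            "power",  0.31, 1.3,   0.85, 0.12,   0.76,
    "leaf_mehg_from_grain", "power",  0.23, 1.3,   0.82, 0.13,   0.71,
    "leaf_mehg_from_stem",  "power",  0.73, 1.1,   0.95, 0.079,  0.90
  )
}

#' Predict an organ concentration from a grain (or stem) concentration
#'
#' Evaluates one of the fitted organ relations: `a * x + b` for linear
#' forms, `a * x^b` for power forms (0 maps to 0).
#'
#' @param input_conc Input concentration, ng/g (>= 0); vectorised.
#' @param relation_id One of the ids in [organ_relations()].
#' @param relations Relation table, defaulting to [organ_relations()];
#'   pass a perturbed copy for Monte Carlo draws.
#' @return Predicted concentration, ng/g.
#' @examples
#' organ_concentration(10, "residues_thg")  # 7.5 * 10 + 34 = 109
#' organ_concentration(1, "residues_mehg")  # 0.27
#' @export
organ_concentration <- function(input_conc, relation_id,
                                relations = organ_relations()) {
  if (any(input_conc < 0)) stop("input concentration must be >= 0", call. = FALSE)
  r <- relations[relations$relation_id == relation_id, ]
  if (nrow(r) != 1L) {
    stop("unknown relation_id '", relation_id, "'; valid ids: ",
         paste(organ_relations()$relation_id, collapse = ", "), call. = FALSE)
  }
  if (r$form == "linear") {
    r$a * input_conc + r$b
  } else {
    ifelse(input_conc == 0, 0, r$a * input_conc^r$b)
  }
}

#' Perturb the organ-relation coefficients for one Monte Carlo draw
#'
#' Draws each `a` and `b` from a normal centred on the fitted value with
#' the fitted standard error, truncating `a` to stay positive (power-law
#' amplitudes and the linear slopes are physically nonnegative). The
#' correlation between `a` and `b` within a fit is not reported and is
#' ignored.
#'
#' @param relations Relation table (default [organ_relations()]).
#' @return A relation table of the same shape with perturbed `a`, `b`.
#' @export
perturb_relations <- function(relations = organ_relations()) {
  relations$a <- vapply(seq_len(nrow(relations)), function(i) {
    draw_dist(dist_normal_trunc(relations$a[i], relations$a_se[i],
                                lower = 1e-12), 1L)
  }, numeric(1))
  relations$b <- stats::rnorm(nrow(relations), relations$b, relations$b_se)
  relations
}

#' Fit an organ relation of either functional form
#'
#' Estimates the coefficients of an organ relation from paired organ
#' concentrations: ordinary least squares of `y` on `x` for the linear
#' form (`a * x + b`), or the log-log regression of [fit_power_law()] for
#' the power form (`a * x^b`).
#'
#' @param x,y Paired concentrations, ng/g (>= 3 pairs; positive for the
#'   power form).
#' @param form `"power"` or `"linear"`.
#' @return List with `a`, `b`, `a_se`, `b_se`, `r2`, `p`, `n` (for the
#'   linear form `a` is the slope and `b` the intercept).
#' @export
fit_organ_relation <- function(x, y, form = c("power", "linear")) {
  form <- match.arg(form)
  if (form == "power") return(fit_power_law(x, y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in the regressor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  list(a = co[2, 1], b = co[1, 1], a_se = co[2, 2], b_se = co[1, 2],
       r2 = sm$r.squared, p = co[2, 4], n = length(x))
}

#' Bulk residue concentration from stem and leaf
#'
#' Rice residues are taken as 3 parts stem to 1 part leaf, so the bulk
#' residue concentration is `(3 * stem + leaf) / 4`. Used when a direct
#' bulk-residue measurement is unavailable but stem and leaf are measured.
#'
#' @param stem,leaf Concentrations, ng/g (>= 0).
#' @return Bulk residue concentration, ng/g.
#' @export
bulk_residue_from_organs <- function(stem, leaf) {
  if (any(stem < 0) || any(leaf < 0)) {
    stop("organ concentrations must be >= 0", call. = FALSE)
  }
  (3 * stem + leaf) / 4
}

#' Residue dry mass from its total nitrogen content
#'
#' National residue masses are estimated from statistical totals of
#' nitrogen in rice residues: `mass = total_N / nitrogen_content`, with the
#' literature-average nitrogen content of 6.5 per mille of dry mass.
#'
#' @param total_n Total nitrogen in residues, Mg/yr (>= 0).
#' @param nitrogen_content Nitrogen mass fraction of residue dry mass,
#'   default `0.0065` (SD 0.0011).
#' @return Residue dry mass, Mg/yr.
#' @export
residue_mass_from_nitrogen <- function(total_n, nitrogen_content = 0.0065) {
  if (any(total_n < 0)) stop("total nitrogen must be >= 0", call. = FALSE)
  if (nitrogen_content <= 0 || nitrogen_content >= 1) {
    stop("nitrogen_content must be in (0, 1)", call. = FALSE)
  }
  total_n / nitrogen_content
}

#' Default residue parameters
#'
#' Literature defaults: residue nitrogen content 6.5 +/- 1.1 per mille of
#' dry mass; rice straw/grain ratio 1.5 (range 0.75-2.5); default THg
#' concentration for crops without measurements 42 ng/g (range 1-180).
#'
#' @return Named list `nitrogen_content`, `nitrogen_sd`,
#'   `straw_grain_ratio`, `straw_grain_range`, `default_other_crop_thg`,
#'   `other_crop_thg_range`.
#' @export
residue_params <- function() {
  list(
    nitrogen_content = 0.0065,
    nitrogen_sd = 0.0011,
    straw_grain_ratio = 1.5,
    straw_grain_range = c(0.75, 2.5),
    default_other_crop_thg = 42,
    other_crop_thg_range = c(1.0, 180)
  )
}

#' THg sequestered in the residues of a (non-rice) crop
#'
#' Residue mass from the straw/grain ratio times the residue THg
#' concentration: `production * ratio * conc * 1e-6` kg/yr.
#'
#' @param production Crop production, Mg/yr (>= 0).
#' @param straw_grain_ratio Residue-to-grain mass ratio (>= 0).
#' @param conc Residue THg concentration, ng/g (>= 0); default 42.
#' @return THg in crop residues, kg/yr.
#' @export
other_crop_residue_thg <- function(production, straw_grain_ratio = 1.5,
                                   conc = 42) {
  if (any(production < 0) || any(straw_grain_ratio < 0) || any(conc < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  production * straw_grain_ratio * conc * 1e-6
}

#' Scale a reference-decade flux by a regional enrichment factor
#'
#' Historical fluxes are obtained by scaling the 2010s-reference flux with
#' region- and year-specific soil mercury enrichment factors (an input
#' series from an external box model; EF = 1 in the reference decade).
#' Years outside the series support are an error: no extrapolation.
#'
#' @param flux_reference Flux in the reference decade, kg/yr.
#' @param series Tibble `region`, `year`, `ef` with `ef > 0`.
#' @param region,year The lookup keys.
#' @return Scaled flux, kg/yr.
#' @export
apply_enrichment <- function(flux_reference, series, region, year) {
  stopifnot(all(c("region", "year", "ef") %in% names(series)))
  if (any(series$ef <= 0)) stop("enrichment factors must be positive", call. = FALSE)
  row <- series[series$region == region & series$year == year, ]
  if (nrow(row) != 1L) {
    stop("no enrichment factor for region '", region, "', year ", year,
         " (no extrapolation outside the series support)", call. = FALSE)
  }
  flux_reference * row$ef
}
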