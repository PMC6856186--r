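# Per-capita probable weekly intake and dose-response health impacts.

#' Continental average adult body weights
#'
#' @return Named numeric vector, kg: Africa 61, Asia 58, Europe 71,
#'   North America 81, Oceania 74, South America 68.
#' @export
continent_body_weights <- function() {
  c(Africa = 61, Asia = 58, Europe = 71, `North America` = 81,
    Oceania = 74, `South America` = 68)
}

#' Dose-response coefficients for the health impact models
#'
#' The IQ model multiplies three epidemiological slopes: `gamma` (IQ points
#' per ug Hg/g maternal hair), `lambda` (ug Hg/g hair per ug Hg/L blood)
#' and `beta` (ug Hg/L blood per ug Hg/day intake). The cardiovascular
#' model uses `phi` (fatal-heart-attack risk per ug Hg/g hair) through a
#' saturating exponential, gated by a Bernoulli causal-association
#' indicator with probability `omega_prob` (default 1/3), and offsets
#' intake against the baseline year by `lag_years` (central 6, range 2-12).
#' The slope values are not part of this package's own estimation; the
#' defaults are the central epidemiological values commonly used with this
#' model family and every ratio-based test is coefficient-free.
#'
#' @param gamma,lambda,beta,phi Nonnegative dose-response slopes.
#' @param omega_prob Probability the cardiovascular association is causal.
#' @param lag_years Intake-to-response lag, years.
#' @param gamma_se,lambda_se,beta_se,phi_se Standard errors for Monte Carlo
#'   perturbation (truncated at zero).
#' @param lag_range Lag range sampled in the Monte Carlo.
#' @return Object of class `ricehg_health_coefficients`.
#' @export
health_coefficients <- function(gamma = 0.3, lambda = 0.25, beta = 0.06,
                                phi = 0.066, omega_prob = 1 / 3,
                                lag_years = 6,
                                gamma_se = 0.1, lambda_se = 0.05,
                                beta_se = 0.01, phi_se = 0.02,
                                lag_range = c(2, 12)) {
  stopifnot(gamma >= 0, lambda >= 0, beta >= 0, phi >= 0,
            omega_prob >= 0, omega_prob <= 1, lag_years > 0,
            length(lag_range) == 2L, lag_range[1] <= lag_range[2])
  structure(list(gamma = gamma, lambda = lambda, beta = beta, phi = phi,
                 omega_prob = omega_prob, lag_years = lag_years,
                 gamma_se = gamma_se, lambda_se = lambda_se,
                 beta_se = beta_se, phi_se = phi_se, lag_range = lag_range),
            class = "ricehg_health_coefficients")
}

#' Probable weekly intake from the national food-supply mercury flux
#'
#' `PWI = food_hg / population / body_weight / 52 * 1e9`
#' (kg/yr of mercury over persons, kg body weight and 52 weeks, scaled
#' kg -> ug).
#'
#' @param food_hg Mercury supplied as food, kg/yr (>= 0).
#' @param population Persons (> 0).
#' @param body_weight Average body weight, kg (> 0).
#' @return PWI in ug per kg body weight per week.
#' @export
pwi <- function(food_hg, population, body_weight) {
  if (any(food_hg < 0)) stop("food mercury must be >= 0", call. = FALSE)
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(body_weight <= 0)) stop("body weight must be positive", call. = FALSE)
  food_hg / population / body_weight / 52 * 1e9
}

#' Population-weighted global (or regional) average PWI
#'
#' @param pwi_values Per-country PWI, ug kg-1 week-1.
#' @param population Matching populations.
#' @return Weighted mean PWI.
#' @export
global_pwi <- function(pwi_values, population) {
  if (length(pwi_values) == 0L) stop("no countries supplied", call. = FALSE)
  stopifnot(length(pwi_values) == length(population), all(population > 0))
  sum(population * pwi_values) / sum(population)
}

#' Weekly intake from locally consumed rice at a contaminated site
#'
#' Inhabitants of a contaminated area are assumed to eat local rice at the
#' national consumption rate:
#' `PWI = conc * intake * 7 / body_weight / 1000` (ng/g x g/day over a week
#' and body weight, ng -> ug).
#'
#' @param conc Rice MeHg concentration, ng/g (>= 0; pass Monte Carlo draws
#'   for a distribution).
#' @param intake_g_day Daily rice consumption, g/day (>= 0).
#' @param body_weight Body weight, kg (> 0).
#' @return PWI in ug per kg body weight per week (vectorised over `conc`).
#' @export
site_pwi <- function(conc, intake_g_day, body_weight) {
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (intake_g_day < 0) stop("intake must be >= 0", call. = FALSE)
  if (body_weight <= 0) stop("body weight must be positive", call. = FALSE)
  conc * intake_g_day * 7 / body_weight / 1000
}

#' Per-fetus IQ decrement from a MeHg intake increment
#'
#' `dIQ = gamma * lambda * beta * (dPWI * BW / 7)`: the weekly intake is
#' converted to a daily dose (`dPWI * BW / 7`, ug/day) and pushed through
#' the intake -> blood -> hair -> IQ slope chain. Linear in the dose and in
#' each coefficient.
#'
#' @param delta_pwi MeHg PWI increment, ug kg-1 week-1 (>= 0).
#' @param body_weight Body weight, kg.
#' @param coeffs A `ricehg_health_coefficients`.
#' @return IQ points lost per fetus.
#' @export
iq_decrement <- function(delta_pwi, body_weight, coeffs = health_coefficients()) {
  if (any(delta_pwi < 0)) stop("delta PWI must be >= 0", call. = FALSE)
  coeffs$gamma * coeffs$lambda * coeffs$beta * (delta_pwi * body_weight / 7)
}

#' Fatal heart attacks attributable to a MeHg intake increment
#'
#' `dCF = Pf * omega * (1 - exp(-phi * lambda * beta * dPWI * BW / 7))`:
#' the national baseline of fatal heart attacks (age >= 30) scaled by a
#' saturating exponential in the daily dose, gated by the causal-
#' association indicator `omega` (0 or 1). Bounded by `Pf * omega`,
#' increasing and concave in the dose; for small doses it reduces to
#' `Pf * omega * phi * lambda * beta * dose`. The intake year is offset
#' against the baseline year by the coefficient set's lag.
#'
#' @param delta_pwi MeHg PWI increment, ug kg-1 week-1 (>= 0).
#' @param body_weight Body weight, kg.
#' @param baseline_deaths National fatal heart attacks, age >= 30,
#'   persons/yr (>= 0).
#' @param coeffs A `ricehg_health_coefficients`.
#' @param omega Causal-association draw, 0 or 1 (draw from
#'   `dist_bernoulli(coeffs$omega_prob)` in the Monte Carlo).
#' @return Attributable deaths per year.
#' @export
heart_attack_deaths <- function(delta_pwi, body_weight, baseline_deaths,
                                coeffs = health_coefficients(), omega = 1) {
  if (any(delta_pwi < 0)) stop("delta PWI must be >= 0", call. = FALSE)
  if (any(baseline_deaths < 0)) stop("baseline deaths must be >= 0", call. = FALSE)
  if (!all(omega %in% c(0, 1))) stop("omega must be 0 or 1", call. = FALSE)
  dose <- delta_pwi * body_weight / 7
  baseline_deaths * omega *
    (1 - exp(-coeffs$phi * coeffs$lambda * coeffs$beta * dose))
}
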