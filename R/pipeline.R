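# End-to-end pipeline: concentrations -> ledger -> residues & burning ->
# exposure -> health, deterministic core plus Monte Carlo wrapper.

#' Evaluate the full pipeline once, deterministically
#'
#' One pass of the whole chain at fixed inputs: builds the flux ledger from
#' the sheets, trade matrix and national concentrations; derives residue
#' concentrations from grain through the organ relations and residue masses
#' from nitrogen totals; computes field-burning THg emissions; converts
#' food-supply MeHg into per-capita weekly intake; and applies the IQ and
#' fatal-heart-attack dose-response models.
#'
#' @param world A `ricehg_world` (or equivalent list of input tables).
#' @param conc National concentrations (`country`, `thg_ng_g`,
#'   `mehg_ng_g`); defaults to the analysis-path estimate from the world's
#'   records via [country_grain_concentration()].
#' @param relations Organ-relation coefficients (perturb for Monte Carlo).
#' @param eparams Emission parameters ([emission_params()]).
#' @param coeffs Health coefficients ([health_coefficients()]).
#' @param omega Causal-association indicator for the cardiovascular model.
#' @param nitrogen_content Residue nitrogen mass fraction.
#' @return List with `ledger`, per-country `exposure` and `health` tibbles,
#'   and `summary`, a named vector of the headline global quantities:
#'   grain/residue THg and MeHg (Mg/yr), burning emission (Mg/yr),
#'   population-weighted PWI (ug kg-1 week-1), per-fetus IQ decrement,
#'   attributable heart-attack deaths, and the trade-embodied MeHg share.
#' @export
evaluate_world <- function(world, conc = NULL,
                           relations = organ_relations(),
                           eparams = emission_params(),
                           coeffs = health_coefficients(),
                           omega = 1,
                           nitrogen_content = 0.0065) {
  if (is.null(conc)) {
    conc <- country_grain_concentration(world$records, world$countries)
  }
  ledger <- build_ledger(world$sheets, conc, world$trade)

  # residues: mass from nitrogen, concentration from grain via the relations
  rmass <- stats::setNames(
    residue_mass_from_nitrogen(world$residues$residue_n_Mg, nitrogen_content),
    world$residues$country)
  cmap_t <- stats::setNames(conc$thg_ng_g, conc$country)
  cmap_m <- stats::setNames(conc$mehg_ng_g, conc$country)
  cc <- world$sheets$country
  # truncate at zero: a perturbed linear intercept can otherwise predict
  # a (physically impossible) negative residue concentration
  res_thg_conc <- pmax(organ_concentration(unname(cmap_t[cc]), "residues_thg",
                                           relations), 0)
  res_mehg_conc <- pmax(organ_concentration(unname(cmap_m[cc]), "residues_mehg",
                                            relations), 0)
  res_thg_kg <- hg_flux(unname(rmass[cc]), res_thg_conc)
  res_mehg_kg <- hg_flux(unname(rmass[cc]), res_mehg_conc)

  burned <- world$fates[world$fates$fate == "burned_field", ]
  bfrac <- stats::setNames(burned$fraction, burned$country)[cc]
  bfrac[is.na(bfrac)] <- 0
  emission_kg <- burning_emission(unname(rmass[cc]) * unname(bfrac),
                                  eparams, res_thg_conc)

  # exposure
  demo <- world$demographics
  fd <- ledger$food
  fd_m <- fd[fd$species == "MeHg", ]
  fd_t <- fd[fd$species == "THg", ]
  i <- match(cc, demo$country)
  pop <- demo$population[i]; bw <- demo$body_weight_kg[i]
  pwi_m <- pwi(stats::setNames(fd_m$food_kg, fd_m$country)[cc], pop, bw)
  pwi_t <- pwi(stats::setNames(fd_t$food_kg, fd_t$country)[cc], pop, bw)
  exposure <- tibble::tibble(country = rep(cc, 2L),
                             species = rep(c("THg", "MeHg"),
                                           each = length(cc)),
                             pwi = c(unname(pwi_t), unname(pwi_m)))

  # health (MeHg only)
  base <- stats::setNames(world$baselines$fatal_heart_attacks_ge30,
                          world$baselines$country)[cc]
  iq <- iq_decrement(unname(pwi_m), bw, coeffs)
  hearts <- heart_attack_deaths(unname(pwi_m), bw, unname(base), coeffs,
                                omega = omega)
  health <- tibble::tibble(country = cc, iq_points = iq,
                           heart_deaths = hearts)

  share <- trade_embodied_share(ledger, species = "MeHg")$global
  fx <- ledger$fluxes
  prod_kg <- function(sp) sum(fx$flux_kg[fx$term == "production" &
                                           fx$species == sp])
  summary <- c(
    grain_thg_mg = prod_kg("THg") / 1000,
    grain_mehg_mg = prod_kg("MeHg") / 1000,
    residue_thg_mg = sum(res_thg_kg) / 1000,
    residue_mehg_mg = sum(res_mehg_kg) / 1000,
    burning_thg_mg = sum(emission_kg) / 1000,
    global_pwi_mehg = global_pwi(unname(pwi_m), pop),
    global_pwi_thg = global_pwi(unname(pwi_t), pop),
    iq_points = global_pwi(iq, pop),  # population-weighted per-fetus IQ
    heart_deaths = sum(hearts),
    trade_share_mehg = share
  )
  list(ledger = ledger, exposure = exposure, health = health,
       residue = tibble::tibble(country = cc, residue_mass_Mg = unname(rmass[cc]),
                                thg_kg = res_thg_kg, mehg_kg = res_mehg_kg,
                                burning_kg = emission_kg),
       summary = summary)
}

#' Run the pipeline with Monte Carlo uncertainty propagation
#'
#' Wraps [evaluate_world()] in the Monte Carlo protocol: national grain
#' concentrations are drawn log-normally around their medians with the
#' record (or default 65%) dispersion; every country's balance sheet is
#' scaled by one uniform 30%-deviation factor (one factor per country so
#' sheet closure is preserved draw by draw); the organ-relation and
#' dose-response coefficients are perturbed normally within their standard
#' errors (amplitudes truncated at zero); the causal-association indicator
#' is Bernoulli(1/3); and the lag is drawn uniformly over its range. Each
#' scalar summary is reported as a median with an interquartile envelope.
#'
#' @param world A `ricehg_world`.
#' @param config A `ricehg_config` (draw count, seed, envelope bounds).
#' @param conc Optional fixed concentration table; default is the
#'   analysis-path estimate.
#' @return List with `deterministic` (the [evaluate_world()] result at
#'   central values) and `envelopes` (a `ricehg_envelopes` tibble).
#' @export
run_pipeline <- function(world, config = run_config(), conc = NULL) {
  stopifnot(inherits(world, "ricehg_world"), inherits(config, "ricehg_config"))
  if (is.null(conc)) {
    conc <- country_grain_concentration(world$records, world$countries)
  }
  det <- evaluate_world(world, conc = conc)

  specs <- list()
  for (i in seq_len(nrow(conc))) {
    specs[[paste0("thg_", conc$country[i])]] <-
      dist_lognormal(conc$thg_ng_g[i], conc$thg_gsd[i])
    specs[[paste0("mehg_", conc$country[i])]] <-
      dist_lognormal(conc$mehg_ng_g[i], conc$mehg_gsd[i])
  }
  for (ccy in world$sheets$country) {
    specs[[paste0("mass_", ccy)]] <- dist_uniform_cv30(1)
  }
  rel <- organ_relations()
  for (rid in c("residues_thg", "residues_mehg")) {
    r <- rel[rel$relation_id == rid, ]
    specs[[paste0(rid, "_a")]] <- dist_normal_trunc(r$a, r$a_se, lower = 1e-12)
    specs[[paste0(rid, "_b")]] <- dist_normal_trunc(r$b, r$b_se)
  }
  hc <- health_coefficients()
  specs$gamma <- dist_normal_trunc(hc$gamma, hc$gamma_se, lower = 0)
  specs$lambda <- dist_normal_trunc(hc$lambda, hc$lambda_se, lower = 0)
  specs$beta <- dist_normal_trunc(hc$beta, hc$beta_se, lower = 0)
  specs$phi <- dist_normal_trunc(hc$phi, hc$phi_se, lower = 0)
  specs$omega <- dist_bernoulli(hc$omega_prob)
  specs$nitrogen <- dist_normal_trunc(0.0065, 0.0011, lower = 1e-4)

  model <- function(ctx) {
    w <- world
    mult <- vapply(w$sheets$country, function(ccy) ctx[[paste0("mass_", ccy)]],
                   numeric(1))
    for (tm in balance_terms()) w$sheets[[tm]] <- w$sheets[[tm]] * mult
    if (!is.null(w$trade)) {
      # keep the matrix consistent with the scaled export terms
      m_rep <- stats::setNames(mult, w$sheets$country)
      w$trade$quantity_Mg <- w$trade$quantity_Mg *
        unname(m_rep[w$trade$reporter])
      # imports now come from the matrix; rewrite the sheet import term
      agg <- rowsum(w$trade$quantity_Mg, w$trade$partner)
      idx <- match(w$sheets$country, rownames(agg))
      new_imp <- ifelse(is.na(idx), 0, agg[idx, 1])
      delta <- new_imp - w$sheets$import
      w$sheets$import <- new_imp
      w$sheets$food <- pmax(w$sheets$food + delta, 0)  # absorb in food
    }
    w$residues$residue_n_Mg <- w$residues$residue_n_Mg *
      unname(stats::setNames(mult, w$sheets$country)[w$residues$country])
    cdraw <- conc
    cdraw$thg_ng_g <- vapply(cdraw$country,
                             function(ccy) ctx[[paste0("thg_", ccy)]],
                             numeric(1))
    cdraw$mehg_ng_g <- vapply(cdraw$country,
                              function(ccy) ctx[[paste0("mehg_", ccy)]],
                              numeric(1))
    rel2 <- rel
    for (rid in c("residues_thg", "residues_mehg")) {
      k <- rel2$relation_id == rid
      rel2$a[k] <- ctx[[paste0(rid, "_a")]]
      rel2$b[k] <- ctx[[paste0(rid, "_b")]]
    }
    hc2 <- health_coefficients(gamma = ctx$gamma, lambda = ctx$lambda,
                               beta = ctx$beta, phi = ctx$phi,
                               omega_prob = hc$omega_prob)
    res <- evaluate_world(w, conc = cdraw, relations = rel2,
                          coeffs = hc2, omega = ctx$omega,
                          nitrogen_content = ctx$nitrogen)
    res$summary
  }

  env <- run_mc(model, specs, n_draws = config$n_draws, seed = config$seed,
                probs = config$iqr_bounds)
  list(deterministic = det, envelopes = env)
}

#' Write pipeline results to a run directory
#'
#' Writes `ledger.csv`, `exposure.csv`, `health.csv`, `residue.csv`,
#' `bilateral_flows.csv`, `summary.csv` and `envelopes.json`.
#'
#' @param result List from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- result$deterministic
  utils::write.csv(det$ledger$fluxes, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  utils::write.csv(det$ledger$bilateral,
                   file.path(dir, "bilateral_flows.csv"), row.names = FALSE)
  utils::write.csv(det$exposure, file.path(dir, "exposure.csv"),
                   row.names = FALSE)
  utils::write.csv(det$health, file.path(dir, "health.csv"),
                   row.names = FALSE)
  utils::write.csv(det$residue, file.path(dir, "residue.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(quantity = names(det$summary), value = unname(det$summary)),
    file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(result$envelopes)) {
    write_envelopes(result$envelopes, file.path(dir, "envelopes.json"))
  }
  invisible(dir)
}
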