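# riceHg

Rice is a staple for half the world's population, and rice paddies are
efficient methylmercury (MeHg) production sites. `riceHg` estimates how much
total mercury (THg) and MeHg move through the rice life cycle — grain
harvest, residue generation and burning, international trade, national food
supply — and what that implies for human dietary MeHg exposure and health.
It is written for exposure modellers and environmental mass-balance
analysts who want the full chain as tested, composable functions rather
than a one-off spreadsheet, and it ships a synthetic-world generator so
every stage runs and is testable completely offline.

## The model

**Concentrations.** National grain concentrations come from
literature-style measurement records (median, geometric SD, sample size;
records with n < 3 or sampled before 2000 are excluded). Records without a
reported dispersion get a 65% relative uncertainty, mapped to a log-normal
whose 95% interval is median × [1/1.65, 1.65]. A missing mercury species is
imputed through the fitted power law

    MeHg = 0.80 · THg^0.65      (background sites)
    MeHg = 0.74 · THg^0.67      (contaminated sites)

and countries with no records at all receive ordinary-kriging predictions
of log concentration from the measured countries (exponential variogram,
great-circle distances, weights constrained to sum to 1).

**Plant partitioning.** Residue (stem + leaf, mixed 3:1) concentrations
follow eight fitted grain-to-organ relations — e.g. residue THg =
7.5·grain + 34 ng/g, residue MeHg = 0.27·grain^1.1 — and national residue
masses are derived from statistical totals of residue nitrogen divided by
the 6.5‰ nitrogen content of rice residues.

**Material flow.** For each country the ten commodity-balance terms obey

    production − export + stock_variation + import
      = feed + seed + processing + other_uses + food + losses   (Mg/yr)

Each term is converted to a mercury flux (kg/yr = Mg/yr × ng/g × 1e-6).
Domestic terms carry the producer's concentration; every bilateral import
carries the exporter's concentration; domestic sinks draw on the pooled
(mass-weighted) supply, which splits food-supply mercury into domestic- and
import-origin shares. From the ledger come the trade-embodied exposure
share and the per-country change versus an autarky counterfactual.

**Burning.** Field-burning emissions are (R/M) · C · E · 1e-6 kg/yr with
burned residue mass R, moisture divisor M, residue THg concentration C and
combustion efficiency E (default 0.85); the remaining residue mercury is
partitioned across feed, fertilizer, fuels, thatching and field retention.

**Exposure and health.** Per-capita probable weekly intake is
PWI = food_Hg / population / body_weight / 52 × 1e9 (µg kg⁻¹ week⁻¹),
population-weighted for the global figure. Health impacts use the slope
chain γλβ: fetal IQ loss ΔIQ = γλβ·(PWI·BW/7) and fatal heart attacks
ΔCF = Pf · ω · (1 − exp(−φλβ·PWI·BW/7)), with ω a Bernoulli(1/3)
causal-association indicator and a 6-year intake-response lag.

**Uncertainty.** Everything runs through a seeded Monte Carlo (default
10,000 draws): log-normal concentrations, uniform ±30% on statistical
masses (one factor per country so each draw's sheet still closes), normal
perturbation of fitted coefficients, Bernoulli ω. Results are reported as
median and interquartile envelope.

## Worked example

```r
library(riceHg)

# a 30-country synthetic world, calibrated so global grain THg is 5.3 Mg
w    <- calibrate_to_paper(generate_world(world_config(seed = 1)), 5.3)
conc <- country_grain_concentration(w$records, w$countries)
res  <- run_pipeline(w, run_config(n_draws = 2000, seed = 1), conc = conc)

round(res$deterministic$summary, 4)
#>     grain_thg_mg    grain_mehg_mg   residue_thg_mg  residue_mehg_mg
#>           4.0067           1.6289          77.5536           0.7272
#>   burning_thg_mg  global_pwi_mehg   global_pwi_thg        iq_points
#>           6.9712           0.0806           0.1983           0.0035
#>     heart_deaths trade_share_mehg
#>        6669.9251           0.1063
```

The deterministic grain THg (4.0 Mg) sits below the calibrated 5.3 Mg
because the analysis path re-estimates national concentrations from noisy
records and kriging rather than using the generator's latent values; the
Monte Carlo envelope (`res$envelopes`) brackets it, e.g. grain THg median
4.22 Mg with interquartile range 3.87–4.69 Mg, and the trade-embodied MeHg
share is 0.106 (10.6% of food-supply MeHg of foreign origin) against the
generator's configured ~10% trade intensity. `res$deterministic$exposure`
and `...$health` hold the per-country PWI, IQ and heart-attack tables.

The same run is available from a shell:

```sh
Rscript exec/ricehg generate --seed 1 --out world/
Rscript exec/ricehg run --in world/ --draws 2000 --seed 1 --out run1/
Rscript exec/ricehg report --in run1/
```

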