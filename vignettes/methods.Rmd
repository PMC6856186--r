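---
title: "Methods: mercury biotransport through the rice life cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mercury biotransport through the rice life cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceHg)
```

`riceHg` chains five models: national grain mercury concentrations,
plant-organ partitioning, a commodity mass balance with bilateral trade,
residue-fate and burning emissions, and dietary exposure with dose-response
health impacts, all wrapped in a seeded Monte Carlo. This vignette explains
each stage, its assumptions, the tunable parameters, and the design
decisions taken where the problem was genuinely open.

## Grain concentrations

A concentration record summarises one literature measurement campaign:
country, coordinates, site class, organ, mercury species, median (ng/g),
geometric SD, and sample count. Inclusion rules: medians positive, `n >= 3`,
sampled in 2000 or later (the cutoff is configurable via
`validate_records()`). Distributions of rice mercury are treated as
log-normal throughout, so records are sampled as
`rlnorm(log(median), log(gsd))`.

When a record lacks a dispersion estimate we assume a 65% relative
uncertainty. We map this to a log-normal whose central 95% interval is
`median * c(1/1.65, 1.65)`, i.e. `gsd = exp(log(1.65)/qnorm(0.975)) ~ 1.29`.
Other mappings (e.g. 65% as a CV) are defensible; this one keeps the
stated percentage interpretable as a symmetric multiplicative bound and is
isolated in `default_gsd()`.

Within a country, multiple record medians are pooled as the sample-size
weighted median of medians — robust to the occasional extreme campaign,
which matters because national values multiply national production masses.
Contaminated-site records (gold/Hg mining, smelting, chlor-alkali, other
industrial) never enter national surfaces: rice from such sites is treated
as locally consumed, and its exposure is assessed separately through
`site_pwi()`.

A missing species is imputed through the fitted power law
`MeHg = a * THg^b` (`a = 0.80, b = 0.65` background; `a = 0.74, b = 0.67`
contaminated). The rare inverse case (MeHg measured, THg not) inverts the
same law analytically rather than fitting a second regression, so the two
directions are exactly consistent.

### Kriging to unmeasured countries

Countries without records receive ordinary-kriging predictions of log
concentration from measured countries. The variogram is exponential,
fitted to the empirical variogram by least squares weighted by bin pair
counts; when fitting fails or fewer than three bins exist, the fallback is
nugget 0, sill = variance of the values, range = one-third of the domain
diameter. Distances are great-circle kilometres (haversine), appropriate
for a global point set. Kriging weights are constrained to sum to one
(unbiasedness), and with a zero nugget the predictor interpolates the data
exactly; both properties are asserted in the test suite at 1e-9.

Range estimation from a single spatial realization is notoriously
variable: in our recovery simulations a true 2000 km range fitted from one
200-point field can return anywhere from ~700 to ~7000 km, while the
geometric mean over six independent fields lands within 25% of the truth.
The recovery test therefore averages over fields; a single-field assertion
would mostly measure luck.

## Plant partitioning and residues

Eight fitted relations convert grain concentrations to stem, leaf and
bulk-residue concentrations; two are linear (residue THg from grain THg:
`7.5 x + 34`; leaf THg from grain THg: `20 x + 18`), the rest power laws
(e.g. residue MeHg `0.27 x^1.1`). Where stem and leaf are measured but
bulk residue is not, residues mix 3 parts stem to 1 part leaf. At very low
grain THg the linear residue relation's intercept (34 ng/g) dominates, so
residue can exceed grain concentration; the relation is applied as fitted.

National residue dry mass is total residue nitrogen divided by the
nitrogen content of rice residues, 6.5 +/- 1.1 per mille of dry mass — a
statistically grounded alternative to the straw/grain ratio (1.5, range
0.75-2.5), which we retain for non-rice crops via
`other_crop_residue_thg()` with a default residue THg of 42 ng/g
(range 1-180). Historical fluxes scale the 2010s reference by regional
soil-mercury enrichment factors; these are an *input series* (from an
external box model), looked up with no extrapolation outside their support.

## Mass balance and trade attribution

Each country-year satisfies, in milled-equivalent Mg/yr,

```
production - export + stock_variation + import
  = feed + seed + processing + other_uses + food + losses
```

Positive stock variation is a drawdown (adds to supply). Fluxes are
`mass x concentration x 1e-6` kg/yr. Attribution rules:

* production, stock variation and exports carry the producer's own
  concentration;
* each bilateral import carries the exporting partner's concentration
  (one-hop attribution; re-exports are not traced);
* domestic sinks draw on the pooled supply — domestic production net of
  exports plus imports — at its mass-weighted mean concentration, and the
  food term is split into domestic- and import-origin shares in proportion
  to the pool's mercury provenance.

These rules make the ledger closure inherit sheet closure exactly and give
global conservation: summed export fluxes equal summed import-origin
fluxes, per species, to machine precision. When a reporter's bilateral
rows disagree with its export term (common in statistical trade data),
rows are rescaled proportionally, with a message.

The "with versus without trade" statistic needs a counterfactual the data
do not define. Ours: identical food mass, valued at the domestic
production concentration; countries with no production fall back to their
region's production-weighted mean; countries with neither are flagged
undefined. This is the single largest interpretive decision in the
package and is isolated in `trade_delta()`.

## Residue fates and burning

Residue mercury is split across burning in fields, livestock feed,
fertilizer return, domestic fuel, industrial fuel, thatching, and a
left/other remainder that absorbs whatever the named fates do not claim,
so the fate ledger conserves mass to 1e-12 relative. Burning emissions are
`(R/M) * C * E * 1e-6` kg/yr. The moisture term `M` is dimensionally
ambiguous in its source formulation ("moisture content (%)"): dividing a
fresh mass by a moisture *fraction* of 0.125 would inflate the emission
8-fold. We default to the fresh-to-dry reading `M = 1/(1 - moisture)`
(~1.143 at 12.5% moisture), which keeps residue concentrations — reported
on dry mass — applied to dry matter; the literal reading remains available
as `emission_params(interpretation = "as_printed")` for comparison.
Combustion efficiency defaults to `E = 0.85`. MeHg emission from burning
is not computed (the emission model is THg-only).

## Exposure and health

`PWI = food_Hg / population / body_weight / 52 * 1e9` in ug per kg body
weight per week; the global value is population-weighted. Continental body
weights: Africa 61, Asia 58, Europe 71, North America 81, Oceania 74,
South America 68 kg. Contaminated-site exposure uses the national rice
consumption rate (g/day) against local concentrations.

IQ loss is linear in the daily dose through the slope chain
`gamma * lambda * beta`; fatal heart attacks scale the national baseline
(age >= 30) by `omega * (1 - exp(-phi*lambda*beta*dose))`, with `omega` a
Bernoulli(1/3) indicator of whether the cardiovascular association is
causal, and a 6-year (range 2-12) lag between intake and response. The
numerical slope values are epidemiological inputs, not estimated here;
defaults (`gamma = 0.3`, `lambda = 0.25`, `beta = 0.06`, `phi = 0.066`)
are central values used with this model family and are plain function
arguments. Health impacts are computed from MeHg only, and site-level
health outputs are limited to IQ. The attributable dose is the full
rice-derived MeHg PWI (counterfactual of zero rice MeHg).

## Monte Carlo protocol

`run_mc()` draws every named input on its own seeded sub-stream (a hash of
the input's name mixed with the base seed), so adding an output or input
never shifts existing draws, and identical seeds give bit-identical
envelopes. Defaults: 10,000 draws, interquartile (25-75%) envelopes.
Distribution kinds:

* log-normal `(median, gsd)` for concentrations;
* uniform "30% deviation" for statistical-agency masses. Two readings are
  implemented: half-width (`[0.7m, 1.3m]`, default) and strict-CV
  (half-width `0.3*sqrt(3)*m`, giving CV exactly 0.30). They differ
  materially in envelope width, hence the explicit switch;
* truncated normal for fitted coefficients (amplitudes truncated positive;
  the `a`-`b` correlation within a fit is not reported and is ignored);
* Bernoulli for the causal-association indicator.

One uniform mass factor is drawn *per country*, not per balance term:
independent per-term noise would break the mass-balance identity on every
draw, whereas a common within-country factor scales both sides equally.
Perturbed organ relations can predict negative residue concentrations at
low grain THg (the linear intercept is 34 +/- 38); predictions are
truncated at zero. Draws on which the model errors are recorded as failed;
more than 1% failures aborts the run with diagnostics.

## The synthetic world

`generate_world()` emulates the structure of the real inputs: a log-normal
background grain THg field (median 7 ng/g, gsd 2) with exponential spatial
correlation (range 2000 km) over country centroids; MeHg tied to THg by
the background power law; measurement records for 70% of countries with
multiplicative sampling noise (gsd 1.2); populations log-uniform 1e5-1e9;
production from per-capita rates of 0.03-0.15 Mg/person/yr; a tenth of
production exported through a gravity-style allocation (exporter surplus
distributed over partners by population) with exact row-sum repair; sheets
that close exactly by constructing losses as the remainder; fate fractions,
enrichment series and heart-attack baselines with realistic magnitudes.
The generator's latent values (true national concentrations, true
trade-embodied share, computed by its own plain-loop arithmetic) are
written to a separate `ground_truth.json` that the analysis path never
reads, keeping generator/analyzer independence auditable.
`calibrate_to_paper()` rescales all masses by one factor so the
deterministic global grain THg hits a target (default 5.3 Mg); with the
synthetic straw/grain ratio of 1.5 the corresponding residue THg lands
near 80-100 Mg, within the package's documented plausibility band of
20-600 Mg for a calibrated world.

What the generator does *not* emulate: the real 281-territory geography,
within-country spatial heterogeneity, reporting gaps and biases of real
commodity statistics, correlated measurement error between species, and
multi-year dynamics (each world is one year). Passing tests therefore
demonstrate correctness of the accounting, estimation and propagation
machinery — not agreement with any real country's exposure.

## Problem sizes and numerical choices

Tests run worlds of 8-30 countries and Monte Carlo studies of 150-500
draws (5000 for distribution-level checks), chosen so the full suite
completes in a few minutes while keeping Monte Carlo assertions at >= 3
standard errors of slack. Coefficient-recovery studies use 100 seeds of
200 pairs, the size at which the log-log regression's standard errors are
small against the printed coefficients. Closure checks use relative
tolerance 1e-9 against total source mass; fate conservation 1e-12;
kriging weight sums 1e-9. Ties in the weighted median resolve to the
lower order statistic. Envelope quantiles use R's default type-7
interpolation; the quantile-equivariance test uses an odd draw count so
the median is an exact order statistic.

## Known limitations

* One-hop trade attribution: re-exported rice is attributed to the last
  reporter, not the original producer.
* The autarky counterfactual is a modelling convention; other conventions
  (e.g. world-price pooling) would give different regional deltas.
* Processing-sink mercury is booked as a sink, not re-entered into intake.
* No age, sex or socio-economic stratification of exposure; no co-exposure
  from fish or other foods.
* Kriging assumes second-order stationarity of log concentrations; strong
  regional regimes (e.g. contaminated provinces) violate this and are
  excluded rather than modelled.
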