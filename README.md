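# leafscale

Leaf water content and temperature corrections for leaf trait scaling.

## The problem

Bivariate leaf trait relationships follow power laws, `A_L = β·M_L^α`, and
the scaling exponent α for leaf area versus leaf dry mass is famously
unstable: below 1 in some groups ("diminishing returns"), near 1 in others,
above 1 in others still. leafscale implements a metabolic model in which
that instability is a predictable consequence of leaf water content (LWC,
g water per g dry mass) and temperature. Mass-specific rates — photosynthetic
capacity `P_s` and specific leaf area `SLA` — follow

```
ln(B_s) = ln(g) + k1·LWC/(K1 + LWC) − E/(kT)
```

a Michaelis–Menten hydration term (maximum log-gain `k1`, half-saturation
`K1`) times a Boltzmann–Arrhenius temperature factor (activation energy `E`
in eV, `k = 8.617e-5` eV K⁻¹). Moving both terms to the left-hand side
("correcting" the trait) turns the model into a sharp prediction: the
corrected whole-leaf trait equals `g·M_L`, so corrected scaling exponents
should converge onto 1 across growth forms, ecosystems and latitudinal
zones, however much the raw exponents disagree.

The package is aimed at trait ecologists working with compilations in the
TRY/GLOPNET mould: it provides the model, the estimation machinery, the
data harmonization that such compilations need, and a synthetic-data
generator that makes every stage testable against a known truth.

## What's inside

* **Model** — `model_params()`, `water_saturation_term()`,
  `arrhenius_exponent()`, `predict_log_rate()`, `temperature_correct()`,
  `full_correct()`.
* **Scaling machinery** — `sma_fit()` (standardized major axis regression
  with analytic CIs, re-implemented from the classical formulas),
  `sma_slope_test()`, `ols_fit()`, `lowess_curve()`, `curvature_index()`.
* **Non-linear estimation** — `fit_saturation_model()`, `fit_full_model()`
  (separable least squares profiling the half-saturation constant),
  `bootstrap_fit()` (1000-resample non-parametric case bootstrap,
  percentile CIs), `compare_aic()` against a linear-in-LWC alternative.
* **Harmonization** — `derive_traits()`, `lwc_from_ldmc()`,
  `mass_specific_photosynthesis()`, `growing_season_temperature()` (months
  strictly above 4.99 °C), `assign_latitudinal_zone()` (tropical < 25° ≤
  temperate < 50° ≤ boreal), `aggregate_species_site_means()`,
  `filter_records()` with an exclusion log, CSV schema I/O with column
  aliasing.
* **Synthetic data** — `synthetic_config()`, `generate_dataset()`,
  `generate_monthly_climate()`: 3000 species–site records drawn from the
  model itself with documented noise and group structure.
* **Pipeline** — `run_scaling_analysis()` (fit pooled correction, correct,
  SMA per group before/after, isometry tests, curvature),
  `run_predictor_comparison()` (nitrogen vs phosphorus vs water mass as
  whole-leaf predictors), `run_report()` (deterministic CSV + JSON output),
  and a CLI (`inst/scripts/leafscale`) with subcommands
  `simulate / harmonize / fit / scale / compare / report`.

## A worked example

```r
library(leafscale)

cfg <- synthetic_config(seed = 5,
                        lwc_ml_log_slope = c(tropical = -0.5,
                                             temperate = 0,
                                             boreal = 0.4))
records <- generate_dataset(cfg)
run_scaling_analysis(records, trait_pair = "area", grouping = "zone")
```

```
Scaling report: area vs dry mass, grouping = zone (n = 3000)
  correction: k1 = 0.997, K1 = 0.556 g g^-1, E = 0.026 eV
  boreal     n=  750  alpha 1.109 [1.087, 1.131] -> 1.050 [1.028, 1.072]  r2 0.92 -> 0.92
  temperate  n= 1600  alpha 1.037 [1.022, 1.052] -> 1.036 [1.022, 1.051]  r2 0.91 -> 0.92
  tropical   n=  650  alpha 0.935 [0.912, 0.959] -> 1.028 [1.005, 1.052]  r2 0.89 -> 0.91
```

The configuration couples LWC to dry mass differently per zone (drier large
leaves in the tropics, wetter in the boreal zone), producing the familiar
latitudinal spread of raw exponents — diminishing returns in the tropics
(0.94), increasing returns in the boreal zone (1.11). The pooled fit
recovers the generating parameters (true `k1 = 1`, `K1 = 0.6`,
`E = 0.03` eV), and after correction the exponents collapse together near
1 (the residual ~0.04 excess is the expected SMA inflation
`sqrt(1 + σ²)` at noise σ = 0.3; with σ = 0 the corrected exponent is 1 to
ten decimals — see the methods vignette).

```r
run_predictor_comparison(records)
```

ranks water mass above nitrogen and phosphorus as a predictor of whole-leaf
photosynthesis and leaf area, by both r² and a LOWESS curvature index —
the generator builds log-quadratic curvature into the nutrient scalings and
none into water mass.

## Layout

```
R/                 model, scaling, fitting, harmonization, generator, pipeline
tests/testthat/    unit + property + acceptance tests (oracle-checked)
scripts/           acceptance.R
inst/scripts/      leafscale CLI
vignettes/         methods vignette
```
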