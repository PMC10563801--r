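# paleoscape

Estuaries accumulate a sediment archive of their own nutrient history:
the nitrogen stable-isotope ratio (δ15N), carbon isotope ratio (δ13C)
and molar C/N of each dated sediment layer record the nitrogen sources
and processing regime of the water column when that layer was
deposited. `paleoscape` turns scattered sediment cores into that
history. It is written for coastal biogeochemists and estuary managers
who want a pre-monitoring nutrient baseline from cores rather than from
the short instrumental record.

The pipeline has four statistical stages, each exposed as ordinary R
functions:

1. **Geochronology** — event markers from radionuclide profiles (basal
   137Cs → 1953, peak 137Cs → 1963, total-Pb peak → 1974), a
   Bacon/Plum-style Bayesian age–depth model with gamma-autoregressive
   accretion increments, explicit 210Pb influx and supported-level
   parameters sampled by adaptive Metropolis-within-Gibbs, a classical
   CRS (constant-rate-of-supply) model as an independent cross-check,
   and pooling of per-core posteriors into a composite estuary-wide
   chronology: `detect_markers()`, `fit_age_depth()`, `crs_ages()`,
   `composite_chronology()`, `apply_chronology()`.
2. **Isoscapes** — era-binned maps of δ15N, δ13C and C/N by ordinary or
   universal kriging, with Matheron semivariograms, weighted-least-
   squares variogram fitting (spherical, circular, exponential,
   Gaussian, linear ± polynomial drift) and seeded 15%-holdout
   cross-validation for family selection: `empirical_variogram()`,
   `fit_variogram()`, `krige()`, `select_variogram()`,
   `build_isoscapes()`.
3. **Change-point decomposition** — the Pettitt test
   (U_t = Σ_{i≤t} Σ_{j>t} sign(x_j − x_i), K = max|U_t|,
   p ≈ 2·exp(−6K²/(n³+n²))), split linear regression around the change
   year giving a step offset and pre/post slopes, DIF/ABS summaries
   (2010 − 1850 change and 2010 value) and pairing with monitoring-era
   water quality: `pettitt()`, `split_regression()`,
   `decompose_series()`, `dif_abs()`, `fraction_before()`,
   `pair_with_water_quality()`.
4. **Nitrogen budget** — a decadal land-use nitrogen-loading budget
   attributing watershed inputs to fertilizer (net surplus × leaching),
   wastewater (per-capita × septic/sewered attenuation), atmospheric
   deposition (rate × area × (1 − retention) by cover) and livestock
   (count × excretion × (1 − loss)): `nlm_budget()` with coefficients
   in a YAML parameter file.

A synthetic-estuary generator (`scenario_config()`, `gen_sites()`,
`gen_true_field()`, `gen_core_timeseries()`,
`gen_radionuclide_profile()`, `gen_watershed_history()`) produces all
of these inputs with known ground truth, so every estimator is tested
by parameter recovery. `run_simulate()` and `run_all()` tie the stages
into an end-to-end, seed-deterministic pipeline.

## Worked example

Decompose a synthetic harbor-mouth series (45 dated points, 1850–2010,
with a 3 ‰ step injected at 1946 and a 0.05 ‰/yr trend over
1950–1980):

```r
library(paleoscape)
cfg    <- scenario_config(trend_start = 1950)
harbor <- list(x = 0)                      # channel coordinate 0 = mouth
s      <- gen_core_timeseries(harbor, cfg, seed = 11, n_points = 45)
dec    <- decompose_series(s)
dec$pettitt
#> Pettitt: change after 1945 (K = 486, p = 4.94e-07, n = 45)
sprintf("step offset: %.2f permil, slope after: %.3f permil/yr",
        dec$step_offset, dec$slope_after)
#> "step offset: 3.04 permil, slope after: 0.031 permil/yr"
sprintf("DIF = %+.1f permil, ABS = %.1f permil",
        dec$dif_abs$DIF, dec$dif_abs$ABS)
#> "DIF = +4.8 permil, ABS = 10.7 permil"
```

The detected change year (series split after 1945) falls inside the
1946 ± 10 yr harbor-construction window, so the step is attributed to
the inlet; the recovered offset (3.04 ‰) matches the injected step, and
DIF (+4.8 ‰) equals step + trend (3 + 0.05 × 30 = 4.5 ‰) plus noise.
`fraction_before(dec, 1988)` returns 0.86: most of the reconstructed
change predates the start of water-quality monitoring.

The decadal nitrogen budget on the emulated watershed history:

```r
b <- nlm_budget(gen_watershed_history(cfg))
b[b$decade %in% c(1930, 1970, 2010),
  c("decade", "fertilizer", "wastewater", "atmospheric", "livestock", "total")]
#>   decade fertilizer wastewater atmospheric livestock  total
#>     1930      19500       3312       11752     46800  81364
#>     1970     623220       8277       21539     74600 727636
#>     2010     709800      14361       27684     20800 772645
```

Loads are kg N yr⁻¹; livestock dominates the 1930s budget, fertilizer
dominates every decade from 1950 on and supplies >90 % of inputs by
2010.

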