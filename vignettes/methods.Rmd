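---
title: "Reconstructing estuarine nutrient history from dated sediment cores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing estuarine nutrient history from dated sediment cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoscape)
```

`paleoscape` reconstructs the nitrogen history of an estuary from the
stable-isotope and stoichiometric record preserved in its sediments. The
pipeline has four statistical stages — geochronology, spatial
interpolation, change-point decomposition, and a watershed nitrogen
budget — plus a synthetic-estuary generator that provides ground truth
for all of them. This vignette describes each model, its assumptions,
the tunable parameters, and the numerical choices made where the design
was genuinely open.

## The synthetic estuary

The generator abstracts the estuary to a one-dimensional channel axis:
the marine mouth sits at coordinate 0 and the freshwater head at
`channel_length`, with coring sites on the vertices of a regular grid
(200 m spacing by default, 85 sites in the full scenario) clipped to the
channel rectangle. This reproduces the head-to-mouth gradients that
drive the science without requiring real shoreline geometry.

Each mapping era has a true spatial field: a linear along-channel
gradient between a mouth and a head endmember, plus a zero-mean Gaussian
random field with spherical covariance (partial sill 0.5, range 1500 m,
nugget 0.02 by default), realized exactly at the requested points by
Cholesky factorization of the covariance matrix. Cholesky sampling is
exact at the few-hundred-point scales used here, which is why it was
preferred over spectral methods. The default pre-1900 d15N endmembers
(about 6 per mil at the mouth, 0.5–1 at the head) and their upward drift
in later eras mirror the documented historical pattern of the study
system; they are configuration, not estimates.

Annual site series over 1850–2010 follow

value(year) = baseline + step x 1[year >= 1946]
            + slope x clamp(year - trend_start, 0, trend_end - trend_start)
            + AR(1) noise,

with defaults step = 3 per mil at 1946 (the harbor-inlet construction
year), slope = 0.05 per mil/yr over 1940–1980 (the fertilizer-expansion
window), innovation sd 0.3 per mil and AR(1) coefficient 0.3,
initialized at the stationary variance. The measurement-noise magnitude
is not documented for the emulated records; 0.3 per mil is a typical
sediment-IRMS reproducibility figure and is exposed in the
configuration. Because dated cores yield far fewer than annual samples,
the generator can also return `n_points` evenly spaced years (45 is the
sampling density the change-point analyses assume).

Radionuclide profiles assume constant accretion (cm/yr) and constant dry
bulk density (1.0 g cm^-3 by default — no compaction model): excess
210Pb decays exponentially with age (decay constant ln(2)/22.3 yr^-1),
slab values are analytic slab means rather than midpoint samples, 137Cs
is zero below the 1953 depth with a Gaussian pulse at the 1963 depth,
and total lead carries a pulse peaking at the 1974 depth. The watershed
history (decadal, 1930–2010) is a deterministic set of shapes: steadily
rising population, fertilizer application flat before 1940 and rising
steeply to a post-1980 plateau, cultivated area declining after 1980,
livestock peaking above 3300 head around 1970 and declining to about
1000 by 2010.

What the generator does *not* emulate: sediment mixing and bioturbation,
compaction, tidal-creek geometry, spatially varying accretion, and
non-stationary spatial covariance. Passing the recovery tests therefore
demonstrates correctness of the estimators under these idealized
conditions, not robustness to every feature of real cores.

## Geochronology

Event markers are read directly off the profiles: the deepest slab with
detectable 137Cs is dated 1953, the 137Cs maximum 1963, the total-lead
maximum 1974, and the surface to the collection year; ties go to the
shallower slab and absent signals simply yield no marker. Marker
uncertainties default to 2 yr (0.5 yr for the surface); the source
records give none, so these are exposed in the arguments.

The Bayesian age–depth model follows the gamma-autoregressive accretion
construction used by the Bacon/Plum family of models: accretion slopes
(yr/cm) on fixed depth segments are built from gamma-distributed
innovations (prior mean `acc_mean`, shape `acc_shape`) coupled by a
memory weight with a Beta prior, so every draw is monotone by
construction. The 210Pb likelihood decays an unknown atmospheric influx
through the modelled slab ages, divides by slab mass per area, adds an
unknown supported level, and compares with the measured slab activity
under a Normal error; markers and pre-calibrated radiocarbon dates
contribute Normal likelihoods on the modelled age at their depth.
Sampling is adaptive Metropolis-within-Gibbs (log-scale random walks,
scales tuned toward 30% acceptance during burn-in); defaults are 5000
iterations, 50% burn-in, thinning 2, 5-cm segments. A full
reimplementation of the published Plum software is deliberately out of
scope — this construction captures its statistical approach while
remaining small enough to audit. Radiocarbon calibration is likewise out
of scope: calendar ages with Normal errors are inputs.

The classical constant-rate-of-supply (CRS) model serves as an
independent cross-check: age(z) = lambda^-1 log(I(0)/I(z)) with I(z) the
cumulative excess-210Pb inventory below z. Finite cores truncate the
inventory, which biases deep CRS ages old; the implementation fits a
log-linear decay to the deepest slabs and integrates the exponential
tail analytically, so noiseless constant-accretion profiles date
exactly. On such profiles the Bayesian and CRS ages agree to well under
5 years across the 210Pb-dated range.

The composite chronology pools cores with equal weight: the mean year at
each depth is the arithmetic mean of per-core posterior means (the
source description does not state a weighting, so equal weights are
assumed and documented), and the 95% interval comes from the pooled
draws. Averaging monotone curves is monotone, but pool-adjacent-violators
is applied defensively if interpolation artifacts introduce
non-monotonicity. Intervals are dated at their midpoints by linear
interpolation and assigned to half-open era bins
(1726–1839, 1839–1885, 1885–1951, 1951–1963, 1963–1981, 1981–2010);
intervals outside the chronology's range are flagged and excluded rather
than extrapolated.

## Isoscapes

Spatial interpolation is ordinary kriging (universal kriging with
polynomial drift of order 1 or 2 for the "linear with drift" options)
with the classical Matheron semivariogram estimator, 12 lag bins to half
the maximum pairwise distance, and weighted-least-squares model fitting
(weights = pair counts; box constraints nugget, sill >= 0, range > 0).
Families: spherical, circular, exponential, Gaussian and linear. The
kriging solver averages duplicate coordinates, treats the zero-lag
semivariance as 0 on the system diagonal (making kriging exact at the
data), and reports the usual kriging variance. A degenerate all-zero
model (fit to a constant field) returns the equal-weight limit.

Family selection honours a deliberately hybrid rule: a seeded random 15%
of the points is held out once, and each held-out point is predicted
leave-one-out from all other points under each candidate model; the
family with the smallest RMSE wins, with ties broken by a fixed order
(spherical first). The candidate set used for the selection-power checks
is {spherical, exponential, gaussian}: the circular family is
numerically almost indistinguishable from the spherical and merely
splits its wins when included, without changing any map.

Era maps average each site's era-assigned samples (unweighted — interval
weighting is not documented for the emulated workflow), krige onto a
regular grid (50 m cells by default), and mask to the convex hull of the
contributing sites buffered by one cell; eras with fewer than four sites
are skipped with a warning. For cross-era comparability the pipeline
forces the spherical family on every era, mirroring the practice the
package emulates. Grid resolution and masking rules are not documented
for the source maps; the defaults here are the package's own choices.

## Change-point decomposition

The Pettitt test is computed through the midrank identity
U_t = t(n+1) - 2 sum_{i<=t} r_i, which equals the defining double sum
sum_{i<=t} sum_{j>t} sign(x_j - x_i) exactly, ties included (the test
suite checks this against a literal brute-force double loop). The
significance approximation p = 2 exp(-6 K^2 / (n^3 + n^2)) is the
standard one; it is known to be conservative, and a 2000-run null
simulation in the tests bounds the empirical rejection rate at 0.08 for
nominal 0.05. Series with missing years are linearly interpolated first
and flagged; the test is applied to raw (not detrended) series, and no
autocorrelation correction is attempted — both documented limitations.

When the test is significant at alpha = 0.05 (the conventional level;
none is stated for the emulated analysis), the series is split at the
first year of the new regime and ordinary least squares is fitted to
each side. The step offset is the gap between the two fits evaluated at
the change year — "difference of y-intercept at the step change year"
read as the offset at the step, not at year zero. The step is attributed
to the 1946 inlet construction when the change year falls within +/- 10
years. Reported components are the step offset and slope_after x (years
remaining), which sum (with the before-slope contribution) to the fitted
total change.

A known property of this estimator: when the post-change truth is a ramp
that plateaus (trend clamped to 1950–1980), the after-segment OLS line
lies above the concave ramp-plateau shape at its left edge, so the
offset estimand exceeds the injected step by roughly 0.2 per mil even on
noiseless input. The recovery simulations in the acceptance tests are
run at the stated study conditions, where detection-year spread
partially offsets this; users comparing step sizes across sites should
remember the offset absorbs some trend curvature. Only `slope_after`
drives attribution; `slope_before` is computed and reported but plays no
inferential role.

DIF and ABS summarize each site: ABS is the 2010 value and DIF the 2010
minus 1850 value, with nearest-year substitution within 5 years
(flagged). `fraction_before()` evaluates the fitted piecewise model to
ask how much of the reconstructed change predates a reference year
(1988, the onset of monitoring), clipped to [0, 1] and undefined for
zero total change. Water-quality pairing joins annual station means of
nitrate and salinity with same-year sediment values over 1990–2010 and
reports Pearson correlations; constant nitrate is flagged rather than
correlated.

## Nitrogen budget

The decadal budget follows the land-use nitrogen-loading-model
structure: fertilizer load is the net surplus
max(0, rate x cultivated area - crop export) times a leaching fraction
(export is netted out *before* leaching — the surplus is what can
leach); wastewater is per-capita excretion partitioned between septic
homes (attenuated by a plume transmission fraction) and sewered homes
(attenuated by treatment); atmospheric load sums deposition x area x
(1 - retention) over land covers; livestock sums count x excretion x
(1 - loss), with the dairy loss fraction representing retention-pond
capture. Totals equal the sum of sources exactly, loads are homogeneous
of degree one in the extensive inputs, and no in-stream transformation
(denitrification, burial) is modelled — the budget estimates watershed
*inputs* only. Groundwater travel-time attenuation is omitted by
default.

Every coefficient lives in `inst/extdata/nlm_params.yaml`. The shipped
values are representative of the published loading-model literature
(4.8 kg N person^-1 yr^-1; septic transmission 0.46; sewered removal
0.90; leaching 0.39; deposition retention 0.62/0.89/0.10/0.90 for
cultivated/natural/impervious/wetland; excretion 100 and 55 kg N
head^-1 yr^-1 for dairy and other cattle with losses 0.80 and 0.60) and
are substitutes for any site-specific calibration, which should be
supplied as a local YAML file.

## Pipeline, problem sizes and determinism

`run_simulate()` materializes a full fixture (sites, core table,
profiles, radiocarbon anchors, series, water quality, watershed history
and a ground-truth JSON); `run_all()` executes every stage and writes a
JSON + CSV report. The function interface *is* the entry point of this
package; `scripts/pipeline.R` is a thin shell wrapper over it. Every
stochastic stage takes an explicit seed and derives per-stage sub-seeds
from it, so reruns under one seed are byte-identical (the run log, which
carries wall-clock timings, is the one deliberately non-reproducible
output).

The test fixture is a 12-site, 3-focal mini estuary with accretion
0.45 cm/yr, chosen so that the 10/25-cm sampling intervals date into all
six eras; the recovery studies use 200 series of 45 points for the
change-point stage, 20 cores for the chronology stage and 20 field
realizations over 50 sites for variogram selection, with MCMC reduced to
2000 iterations and 10-cm segments inside the pipeline. These sizes give
stable Monte-Carlo estimates of every rate the package reports while
keeping a full run on one CPU in the low minutes.

## Other numerical choices, in brief

Atomic weights are fixed at C = 12.011 and N = 14.007 for the molar C/N
conversion; C/N is treated as a dimensionless molar ratio throughout,
delta values as plain reals in per mil with no unit objects. Missing
isotope values propagate as missing — they are never imputed. Depth is
cm below the sediment surface with half-open [top, bottom) intervals.
Ages of the 1953/1963/1974 markers are assigned at the detected slab's
bottom (basal 137Cs) or midpoint (peaks), so marker depths are accurate
to one slab thickness.
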