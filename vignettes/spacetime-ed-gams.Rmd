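---
title: "Space-time odds-ratio mapping of ED case-control data with loess GAMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time odds-ratio mapping of ED case-control data with loess GAMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emergency-department surveillance streams record, for each visit, a geocoded
residence, a visit date, a complaint syndrome and basic covariates such as
age. Treating one syndrome group as cases and an etiologically unrelated
syndrome group as controls turns such a stream into individual-level
case-control point data, and the question "where and when was the odds of
illness elevated?" becomes a smoothing problem: estimate the log odds of
case status as a smooth function of residence location, adjusted for
covariates, and watch that surface evolve over calendar time.

`edgam` implements this analysis end to end: a loess-smoothed logistic
generalized additive model (GAM) as the estimation engine, AIC selection of
the smoothing span, a chain of overlapping time windows that turns a single
spatial analysis into a movie, permutation tests for whether each map is
flat and where it departs, and rendering of the resulting odds-ratio
surfaces on one shared color scale.

## The model

For records $i = 1, \dots, n$ with binary outcome $y_i$, location
$(x_{1i}, x_{2i})$, study day $t_i$ and covariate vector $z_i$, the two
models are

$$\operatorname{logit} p(t) = S(t) + \gamma' z \qquad (\text{temporal})$$
$$\operatorname{logit} p(x_1, x_2) = S(x_1, x_2) + \gamma' z \qquad (\text{spatial})$$

where $S$ is a loess smooth: at each evaluation point the fitted value is
the intercept of a weighted linear regression over the `span`-fraction
nearest records, with tri-cube weights $(1 - (d/h)^3)^3$ in the distance $d$
to the target scaled by the bandwidth $h$ (the distance to the k-th nearest
neighbour, $k = \lceil \mathrm{span} \cdot n \rceil$). The tri-cube kernel
vanishes at the neighbourhood boundary, which keeps edge bias smaller than a
flat nearest-neighbour window of the same span. The local polynomial degree
is fixed at 1 (local linear), the standard loess choice; it makes the
smoother exactly reproduce any response that is linear in the smoothing
coordinates — a property the test suite exercises at every candidate span.

Fitting is by local scoring. Starting from the covariate-only logistic fit,
each iteration forms the IRLS working response
$\zeta = \eta + (y - \mu)/(\mu(1-\mu))$ and weights $w = \mu(1-\mu)$, then
backfits: a weighted least-squares solve of $\zeta - S$ on $(1, z)$, a loess
smooth of $\zeta - (\alpha + \gamma'z)$ on the smoothing coordinates with
prior weights $w$, and re-centring of $S$ to weighted mean zero with the
centring constant absorbed into the intercept (the identifiability
constraint). Iteration stops when the relative deviance change falls below
`1e-6` or after 50 iterations; the best-deviance iterate is returned, so the
GAM never fits worse than the covariate-only model it nests — the test suite
asserts this nesting on randomized data.

Effective degrees of freedom are `(number of parametric coefficients) +
(smoother trace - 1)`, the trace being the sum of the hat diagonal of the
final smoother; `AIC = deviance + 2 edf`. A per-observation (average
deviance) AIC differs only by the factor $1/n$, which cannot change which
span minimizes it within one dataset, so the simpler deviance-scale form is
used. Span selection fits the GAM over a candidate ladder (default
`0.02-0.10` in steps of 0.01, then `0.15-0.95` in steps of 0.05 — the fine
low end matters because temporal optima of a few percent occur in practice)
and takes the AIC argmin, breaking ties toward the larger span (the
smoother, more conservative map).

Coordinates are used exactly as supplied. Inputs are expected in a planar
projection; longitude/latitude can be used knowingly as planar coordinates,
but the degrees-versus-kilometres anisotropy is then the user's
responsibility, and no internal standardization is applied.

## Overlapping time windows

Temporal smoothing is achieved by windowing rather than by a 3-D smooth, so
that space and time get separately optimized spans instead of a forced
common bandwidth across incommensurable units:

1. Fit the temporal GAM to the whole stream and select its span; the
   window length is `L = ceiling(span * n)` records.
2. The first window holds records 1..L, extended to the end of the L-th
   record's day — whole-day granularity, a day is never split, so `L` is a
   minimum.
3. Fit the temporal GAM to the first window alone; with selected span
   `s`, the inter-window interval is the relative day of the window's
   `ceiling(s * L)`-th record (window's first day = relative day 1).
4. Each later window grows around a target median day (previous target +
   interval) by annexing the nearer adjacent whole day — ties go to the
   earlier day, for determinism — until at least `L` records are included.
5. The chain stops with the first window whose last day is the dataset's
   last day; if the target ladder would overshoot first, the final target
   is clamped to the last day so a closing window always exists. (The
   stop rule alone does not define overshoot behaviour; clamping is this
   package's choice.)

The interval rule uses the *relative* day of the n-th record. For a first
window starting on study day 1 the relative and absolute readings coincide,
which is the only worked configuration available to anchor the convention;
the relative reading is the one that generalizes to later windows.
The median record of a window of length $m$ is record
$\lfloor (m+1)/2 \rfloor$ (record 500 of 1,000).

## Per-window analysis and testing

Each window gets a spatial GAM at its own AIC-selected span, a reduced
(covariate-only) logistic fit, and predictions of adjusted log odds on one
shared rectangular grid spanning the data bounding box. Grid points can be
clipped by a study-area polygon (GeoJSON; even-odd rule, boundary counts as
inside) and by a data-density mask: a point stays active only if at least
`min_points` records lie within `max_mask_distance`. The density mask
matters because loess GAMs are least reliable at low-density edges; leaving
sparse corners active produces spurious extreme odds ratios there.

Predicted odds are converted to odds ratios against the whole window
population: `OR(g) = exp(logodds_full(g) - logodds_reduced)`, both evaluated
at the window's covariate mean (the parametric parts then nearly cancel, and
cancel exactly when the full and reduced coefficient estimates agree).
Because the reference is the population average, a map must show both
elevated and depressed regions; and if a hotspot covers a fraction $q$ of
the window's population at true odds ratio $R$, the expected mapped OR
inside it is $R / (1 - q + qR)$, not $R$ — the reference itself is raised.
This dilution is visible in the recovery simulations below.

The global test of map flatness uses the deviance difference between the
full and reduced fits. Its null distribution comes from conditional
permutation: the coordinate pairs are shuffled among the window's records
while day, outcome and covariates stay attached, breaking only the
location-outcome link given the covariates. The permuted statistic is
computed at the same span as the observed one, and
`p = (1 + #{perm >= obs}) / (n_perm + 1)`, so the smallest attainable p is
`1/(n_perm + 1)` — screening at 0.005 therefore needs more than 199
permutations (the pipeline default is 999; 249 is the smallest round count
used in the simulations). The 0.005 screen is deliberately conservative:
one global test is run per window, and the per-window analyses are many.

Pointwise hot/cold spots reuse the same permutation set: each grid point's
observed log odds is ranked within its permutation distribution (mid-rank
tie handling, which keeps ranks unbiased when the discrete permutation
distribution has ties), and points above the 97.5th / below the 2.5th
percentile are flagged — but flags are only populated when the window's
global test passes the screen (gatekeeping), a guard against reading
pointwise noise on a globally flat map.

One technical note on calibration: the permutation test is exact (the
p-value exactly uniform up to discreteness) when the span is fixed before
permuting. Selecting the span on the observed data and then permuting at
that span — the pipeline's behaviour, the standard practice for this method —
introduces a small anti-conservatism, one of the reasons the conservative
0.005 screen exists. The calibration simulations therefore test the
permutation machinery at a fixed span.

## The synthetic data generator

`synthetic_config()` / `generate_dataset()` simulate an ED-like stream with
known truth: visit days from a winter-peaked sinusoidal intensity whose
peak/trough ratio is `seasonal_amplitude`; locations from a mixture of
population clusters (bivariate normal, truncated to the bounding box) —
emulating the town-clustered geography of real residence data; age from a
truncated normal on [0, 106]; and case status from a Bernoulli draw whose
logit adds a baseline, a linear age effect, and hard-disc hotspot
elevations (optionally smooth Gaussian bumps; the hard disc is the default
because it admits an exact inside/outside contingency-table oracle). Every
record's generative probability is stored, so tests can verify the stream
against its own truth to machine precision. `cape_cod_like_config()`
packages a five-year, 44,421-record, 16%-case-fraction configuration with
coastal-style clusters, matching the scale of a real multi-year surveillance stream
without reproducing any real data.

What the generator does *not* emulate: geocoding error, spatially varying
covariate confounding (e.g. socioeconomic structure), control-group drift
other than a simple controls-only seasonal mode, and day-of-week visit
patterns. Passing recovery tests on this generator therefore demonstrates
that the machinery estimates what it claims under its own assumptions, not
that any particular real-data finding is correct.

## Study designs used in the checks

Three simulation designs are fixed in the test suite and the acceptance
script:

* **Null calibration** — flat risk (no hotspots, no age effect), n = 800
  per replicate, span fixed at 0.5, 99 permutations, 100 replicates: the
  global p-value should be uniform (KS test) and the 0.05-level rejection
  rate inside its binomial band.
* **Recovery** — a disc hotspot of true OR 2 and radius 1.6 centred on a
  dense town cluster holding 8% of the population weight (about 12% of
  records fall inside), over a diffuse background cluster; balanced
  case-control baseline odds 0.9, n = 5,000. The dense-town geometry gives
  the disc interior enough data density for the smoother to resolve it;
  candidate spans {0.03, 0.05, 0.08} put the local bandwidth at or below
  the disc radius (a resolution-matched ladder chosen by the pre-study
  power analysis); the prediction grid is masked to points with at least 10
  records within 0.5 units, the low-density-edge clipping discussed above.
  Under these conditions the mapped OR inside the disc is expected near
  `2 / (1 - q + 2q) ≈ 1.8` before smoothing attenuation, and the observed
  value across replicates is around 1.6; the surface argmax falls inside
  the disc in ≥ 80% of replicates and pointwise hot flags appear inside
  whenever the global screen passes.
* **Determinism** — a 2,000-record stream analyzed end to end twice with
  one seed must give byte-identical summaries and frame images.

Problem sizes in the routine test run (replicate counts, permutation
counts, grid resolutions) are scaled so the whole suite completes in
minutes while leaving each check statistically meaningful; the acceptance
script re-runs the same designs from scratch at its own sizes.

## Numerical choices

* Local solves use the bandwidth-scaled design (coordinates divided by the
  neighbourhood bandwidth) and a Cholesky factorization with a relative
  pivot tolerance of `1e-12`; a rank-deficient local design (all
  neighbours coincident) falls back to the tri-cube weighted mean and is
  counted, with a warning.
* Neighbourhood ties at the boundary break by record order; AIC ties break
  toward the larger span; equidistant day annexation breaks toward the
  earlier day. All three exist for determinism.
* Local scoring: relative deviance tolerance `1e-6`, maximum 50
  iterations, fitted probabilities clamped to `[1e-8, 1 - 1e-8]`;
  non-convergence returns the best iterate with `converged = FALSE`.
* A window containing a single outcome class has a degenerate likelihood
  and raises a typed error; the pipeline records it as a window status and
  continues.
* Permutations derive from a single seed; the (seed, permutation-index)
  pair determines each shuffle, and the C++ permutation path is tested
  equal to an explicit R-level coordinate shuffle.
* The shared display range pools all windows' ORs and is symmetric in log
  OR, clipped at the pooled 1st/99th percentiles.

## Known limitations

* Space and time are smoothed separately (windows, then 2-D smooths); a
  unified space-time smoother with principled joint bandwidth selection is
  out of scope.
* No variance or confidence bands accompany the OR surfaces; inference is
  the global screen plus pointwise permutation ranks, and hot/cold
  contours should be read as exploratory.
* The pointwise flags are not corrected for multiplicity beyond the global
  gatekeeping screen.
* AIC span selection is per window, so consecutive maps can change
  smoothness abruptly.
* Edge bias is mitigated (tri-cube weights, density masking) but not
  eliminated; estimates just inside a masked boundary remain the least
  reliable part of any map.
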