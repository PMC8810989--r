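---
title: "Dating land-to-lagoon conversion from NIR reflectance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating land-to-lagoon conversion from NIR reflectance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagoondate)
```

## The model

A pixel that is converted from vegetated land to an open-water waste lagoon
changes its near-infrared (NIR) surface reflectance regime once and
permanently: water absorbs NIR, land reflects it. We model a cleaned
per-pixel record $x_1, \dots, x_n$ (scaled surface reflectance, 0–10,000)
as piecewise normal with at most one changepoint $\tau$:

$$x_i \sim \mathcal{N}(\mu_1, \sigma_1^2) \; (i \le \tau), \qquad
  x_i \sim \mathcal{N}(\mu_2, \sigma_2^2) \; (i > \tau).$$

`detect_single_changepoint()` minimises the summed segment cost over all
admissible splits. Under `metric = "mean"` (common variance) the segment
cost is the sum of squared deviations from the segment mean — the
twice-negative-profile-log-likelihood up to constants. Under
`metric = "meanvar"` it is $n_k \log\hat\sigma_k^2$ with the
maximum-likelihood segment variance. With exactly one changepoint allowed,
binary segmentation and the at-most-one-change formulation coincide, so the
detector is implemented directly as the single-split argmin: the result is
identical and the implementation is exactly testable against an exhaustive
re-scan. No penalty term appears because the number of changepoints is
fixed at one, not selected.

Assumptions worth keeping in mind:

* **One conversion per pixel.** Lagoons are essentially permanent once
  built; decommissioning, expansion, or other land-use transitions violate
  the single-changepoint model and are out of scope.
* **Normality is assumed but not enforced.** The split minimises a
  normal-likelihood cost; moderately skewed records still place the argmin
  at the dominant level shift, and detection accuracy is driven by the
  step-to-noise ratio rather than distribution shape.
* **The step dominates.** Phenology, moisture and sensor effects add
  variance around the segment means but are assumed smaller than the
  land-to-water step (several thousand scaled-reflectance units versus a
  noise sd of a few hundred).

## The decision workflow

`estimate_construction_year()` maps a fit to an outcome:

1. changepoint year $\le$ `era_start` → `PRE_ERA`;
2. mean of S2 greater than mean of S1 → `PRE_ERA`;
3. otherwise → construction year = calendar year of the first S2
   observation (values beyond `era_end` flagged `post_era`).

Rules 1–3 partition the space of fits, so the workflow is total. Rule 1
exists because a record that starts in 1984 cannot show the
pre-construction state of a lagoon built at the start of the record, and
because the earliest images carry commissioning-era artifact signals that
attract spurious early changepoints; both cases mean "no datable
conversion after `era_start`". Rule 2 catches series whose largest shift is
a reflectance *rise* — the opposite of a land-to-water conversion — which
likewise indicates the lagoon predates the record.

**Changepoint-to-year attribution.** The changepoint could be attributed
to the last pre-change or the first post-change observation; we use the
first S2 observation, because construction is evidenced by the first image
showing water, and the ±1-year validation tolerance absorbs the
alternative convention.

**Era bounds.** `era_start = 1986`, `era_end = 2010` by default: a
1984-onset record needs about two years of pre-conversion imagery for a
reliable split, and symmetric reasoning caps the datable range near the
2012 end of the record. Both are configurable so the workflow transfers to
other sensors.

**Scoring pre-era calls.** How a `PRE_ERA` prediction should be credited
against observed years just at the era boundary is genuinely ambiguous. We
adopted: `PRE_ERA` is correct iff the observed year is $\le$ `era_start`;
a `YEAR` prediction against a pre-era truth is correct iff the predicted
year is $\le$ `era_start + tolerance`. The convention is embedded in every
`accuracy_report` (`$pre_era_rule`) rather than silently applied.

## Cleaning

`remove_bright()` drops values strictly greater than 10,000 — physically
impossible surface reflectance caused by clouds and other bright
contamination. The strict inequality (10,000 retained) makes the rule
exact and idempotent.

The field's processing descriptions rarely pin down "linear filtering", so
`linear_filter()` commits to the simplest linear smoother consistent with
noise reduction: a centred moving average, default `window = 3`
observations, truncating at record edges (the mean over the available
neighbours; for `[1,2,3,4,5]` with window 3 the output is
`[1.5, 2, 3, 4, 4.5]`). Filtering operates on observation index rather
than calendar time, mirroring per-image processing of an irregularly
thinned acquisition record; `window = 1` disables it. Outlier removal runs
*before* filtering — removal targets exactly the values the filter would
otherwise smear into neighbours.

## Numerical choices

* **Variance floor.** `meanvar` costs use
  $\log \max(\hat\sigma_k^2, 10^{-8})$; a flat synthetic segment would
  otherwise give $\log 0$. A floored segment flags the fit degenerate.
* **Tie-break.** Cost ties resolve to the smallest $\tau$ (a constant
  series yields $\tau = 0$, flagged degenerate since the segment means
  coincide).
* **Degeneracy.** $|\bar x_{S1} - \bar x_{S2}| < 10^{-8}$ marks "no
  meaningful change"; the floor is configurable.
* **Minimum segment lengths.** 1 for `mean`, 2 for `meanvar` (a one-point
  segment has no variance).
* **Prefix sums.** The production detector computes all split costs from
  cumulative sums and squares in one vectorised pass; the test suite holds
  it to *exact argmin agreement* with an $O(n^2)$ re-scan that recomputes
  both segment costs from raw values, on 1,000 random series per run.

## Geodesic distances

`nearest_water_distance()` works on the WGS84 ellipsoid throughout
(`geosphere::distGeo()`; polygon areas via `geosphere::areaPolygon()`). A
site inside a polygon is at distance 0 (even-odd containment). For a site
outside, each boundary segment is densified to candidate points at most
`densify_m` apart (default 500 m), the best candidate is located, and the
distance is refined by a bounded one-dimensional minimisation of the
ellipsoidal distance along the neighbouring chord. On rectangle fixtures
with analytically known nearest boundary points the result agrees with a
direct ellipsoidal solve to well under 1 m, and halving `densify_m`
changes distances by far less than 1 m.

The area filter (`filter_water_features()`, default 0.05 km², strict)
applies to polygons only. Hydrography polylines carry no area, so they are
always retained; treating "area below threshold" as applying to lines
would silently delete every stream. Manual reclassification of
misidentified hydrography features is supported by excluding feature ids
from the input table, not automated.

## Mann–Kendall trend

`mann_kendall()` computes $S = \sum_{i<j} \mathrm{sign}(x_j - x_i)$, the
tie-corrected variance
$\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$, a
continuity-corrected $Z$, and a two-sided normal p-value; the trend is
called at `alpha` (default 0.05). In the workflow it is applied to *annual
median* nearest-water distances (`annual_median_distance()`), one value
per construction year, though the function is generic over any ordered
series. An all-tied series is degenerate: $S = 0$, no trend, flagged.

For small series the normal approximation can be checked against the
exact permutation null by full enumeration:

```{r envelope, eval = FALSE}
perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(p >= i, p + 1L, p))
  }))
}
mk_S <- function(x) sum(vapply(seq_along(x)[-length(x)], function(i)
  sum(sign(x[-(1:i)] - x[i])), numeric(1)))
envelope <- function(n) {
  Svals <- apply(perms(n), 1, function(idx) mk_S(seq_len(n)[idx]))
  max(vapply(sort(unique(abs(Svals))), function(s0) {
    p_exact <- mean(abs(Svals) >= s0)
    p_norm <- if (s0 == 0) 1 else
      2 * pnorm(-(s0 - 1) / sqrt(n * (n - 1) * (2 * n + 5) / 18))
    abs(p_norm - p_exact)
  }, numeric(1)))
}
sapply(4:8, envelope)
```

Running this enumeration gives a maximum two-sided discrepancy of 0.0252
at $n = 4$, shrinking monotonically to 0.0123 at $n = 8$; the test suite
asserts agreement within 0.03 on all-distinct series of these lengths and
re-derives $S$ and $\mathrm{var}(S)$ from the hand formulas.

## What the simulator emulates — and what it does not

`simulate_series()` reproduces the statistical skeleton of a
Landsat-5-like record: a 16-day nominal cadence over 1984–2012,
independent per-acquisition dropout (cloud and quality screening),
additive Gaussian noise around the segment means, bright outliers drawn
strictly above 10,000 (so the cleaning rule removes exactly the injected
contamination, making the cleaning stage testable by count), a step from a
vegetated mean (default 3,500) to a water mean (default 800) whose first
on-or-after-change observation already shows water, and an optional 1984
artifact segment whose magnitude is a free parameter (default 1,200) —
the artifact is real in early-record imagery but its amplitude is not
quantified, so the simulator exposes it rather than asserting a value.
Default noise sd 300 and dropout 0.2 are in line with a cloud-screened
Coastal Plain record retaining roughly 120 usable images per site over 29
years.

It deliberately omits: phenological seasonality and autocorrelation,
radiative-transfer realism, multi-band structure, gradual multi-year
construction ramps, lagoon decommissioning or expansion, and
partial-pixel mixing of small lagoons. Passing the simulation-based tests
therefore demonstrates that the algorithmic chain is correct under its own
model — an abrupt, persistent, dominant step — not that real-imagery
accuracy will match the synthetic recovery rate; real records add the
error sources listed above.

`simulate_landscape()` places sites and simple rectangular/linear water
features uniformly at random: it exercises the geometry code, but encodes
no relationship between construction year and siting, so trend results on
fully synthetic landscapes are null by construction.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 1,000 (tests) / 500
(script) random series of $n \le 60$ for oracle equivalence; a 500-site
(tests) / 340-site (script) synthetic validation cohort with change years
uniform on 1987–2009 for parameter recovery, scored at ±1 year; 200
replicates for pre-era routing; 50 for the deterministic inverted-change
rule. All randomness flows from a single seed; per-site substreams are
derived deterministically from (seed, site id), so collections are
reproducible element-wise. Calendar dates are used everywhere
(ISO-8601 in files); `decimal_year()` exists for plotting only.

## Known limitations

* A site whose record is emptied by cleaning, or is shorter than twice the
  minimum segment length, cannot be dated; `run_pipeline()` skips it and
  reports it rather than failing the batch.
* The `meanvar` metric is retained behind a flag but `mean` is the
  default: on step-change records the variance term adds sensitivity to
  heteroscedastic noise without improving localisation of the step.
* Distances use point lagoon coordinates, not lagoon polygons; densities
  use even-odd point-in-polygon with boundary sites assigned to the first
  containing polygon in stable id order.
* GeoJSON support is a narrow contract (Point / Polygon-exterior-ring /
  LineString FeatureCollections in WGS84) — enough to carry sites,
  waterways and watershed polygons exported from national hydrography
  products; it is not a general-purpose GIS reader.
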