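# lagoondate

Open-air animal waste lagoons are, to a satellite, small ponds: water
absorbs strongly in the near infrared (NIR) while cropland, pasture and
forest reflect. When a pixel is converted from vegetated land to a lagoon,
its NIR surface reflectance record drops abruptly — from roughly 3,000–4,000
down to a few hundred on the 0–10,000 scaled-reflectance convention. Given a
per-pixel reflectance time series spanning the conversion, the year the
lagoon was built can therefore be recovered as a changepoint.

`lagoondate` implements that workflow end to end for people studying the
historical expansion of concentrated animal feeding operations (CAFOs) and
its environmental footprint:

1. **Cleaning** — observations with scaled reflectance above 10,000
   (clouds, bright artifacts) are removed; a centred moving-average linear
   filter reduces residual noise.
2. **Changepoint detection** — the single best split of the series into
   segments S1/S2 under a normal likelihood. With `metric = "mean"` the
   cost of a segment is its sum of squared deviations from the segment
   mean, `sum_k (x_i - mean_k)^2`; with `metric = "meanvar"` it is
   `n_k * log(max(sigma2_k, eps))` with the maximum-likelihood segment
   variance. The fitted changepoint is the split `tau` minimising
   `C(S1) + C(S2)` over all admissible splits (at-most-one-change; with a
   single changepoint allowed, binary segmentation reduces to exactly this
   argmin).
3. **Decision workflow** — a changepoint in or before `era_start` (default
   1986), or a series whose mean *rises* at the split, is classed
   `PRE_ERA` (built at or before the first reliably observable year);
   otherwise the construction year is the calendar year of the first S2
   observation.
4. **Validation** — estimates are scored against observed construction
   years with a ±1-year tolerance.
5. **Spatial stage** — hydrography features below 0.05 km² are dropped,
   geodesic (WGS84 ellipsoid) nearest-water distances are computed per
   lagoon, summarised by construction cohort, tested for monotonic trend
   with the Mann–Kendall statistic `S = sum_{i<j} sign(x_j - x_i)`
   (tie-corrected variance, continuity-corrected normal Z), and lagoon
   density is aggregated per 100 km² of watershed polygon.
6. **Synthetic data** — a simulator generates Landsat-5-like B4 records
   (16-day cadence, cloud dropout, bright outliers, an optional
   early-record 1984 artifact) with known ground truth, so every stage is
   testable without satellite data.

## Worked example

Simulate a lagoon built in June 1994, observed 1984–2012 at a 16-day
cadence with noise sd 300, 20 % cloud dropout and 1 % bright outliers, then
date it:

```r
library(lagoondate)

sc <- series_scenario(site_id = "lagoon_042", change_date = "1994-06-01",
                      noise_sd = 300, dropout_prob = 0.2, outlier_prob = 0.01,
                      seed = 42L)
raw <- simulate_series(sc)        # 531 observations survive dropout

fit <- raw |>
  remove_bright() |>              # drops values > 10,000
  linear_filter(window = 3) |>
  detect_single_changepoint(metric = "mean")
fit
#> <changepoint_fit> site lagoon_042 (mean, n = 524)
#>   tau = 182 -> 1994-06-05
#>   S1 mean 3494.9, S2 mean 796, cost 17666100

estimate_construction_year(fit)
#> # A tibble: 1 × 4
#>   site_id    kind   year flag
#>   <chr>      <chr> <int> <chr>
#> 1 lagoon_042 YEAR   1994 <NA>
```

The detector finds the split after observation 182 (0-based), whose first
post-change image is 1994-06-05 — four days after the true conversion — and
the workflow dates the construction to 1994. `run_pipeline()` applies the
same chain to a many-site table and returns one estimate per site;
`score_validation()` compares a batch of estimates to observed years.

The trend stage works on any ordered series, e.g. annual median
nearest-water distances (metres):

```r
mann_kendall(c(192, 237, 231, 230, 239, 262, 314))
#> <mann_kendall> n = 7, S = 15, tau = 0.714, Z = 2.103, p = 0.0355 -> INCREASING
```

Here 15 of 21 year pairs are increasing, and the continuity-corrected
normal approximation puts the two-sided p at 0.036: distances grew
significantly over the period.

A command-line interface wrapping the same functions ships in
`inst/cli/lagoondate.R` (subcommands `simulate`, `clean`, `detect`,
`estimate`, `validate`, `distances`, `cohorts`, `trend`, `density`, `run`).

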