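#' Simulate one near-infrared reflectance time series
#'
#' Generates a Landsat-5-like band-4 surface reflectance record for a single
#' site: acquisitions every `cadence_days` from `record_start`, a step from
#' `pre_mean` down (or up) to `post_mean` at `change_date`, additive Gaussian
#' noise, independent per-observation cloud dropout, occasional bright
#' outliers above 10,000, and optionally a distinct 1984 artifact mean.
#'
#' The first observation dated on or after `change_date` already takes the
#' post-change mean: construction is evidenced by the first image showing
#' water. The same scenario (including its seed) always produces the same
#' series.
#'
#' @param scenario A [series_scenario()].
#' @return A tibble with columns `site_id`, `date` (Date) and `value`
#'   (scaled surface reflectance), sorted by date.
#' @examples
#' sc <- series_scenario(noise_sd = 0, dropout_prob = 0, outlier_prob = 0)
#' simulate_series(sc)
#' @export
simulate_series <- function(scenario) {
  stopifnot(inherits(scenario, "series_scenario"))
  dates <- seq(scenario$record_start, scenario$record_end,
               by = scenario$cadence_days)
  n <- length(dates)

  base <- rep(scenario$pre_mean, n)
  if (scenario$artifact_1984) {
    base[format(dates, "%Y") == "1984"] <- scenario$artifact_mean
  }
  if (!is.na(scenario$change_date)) {
    base[dates >= scenario$change_date] <- scenario$post_mean
  }

  withr_seed <- scenario$seed
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(withr_seed)

  value <- base + stats::rnorm(n, 0, scenario$noise_sd)
  is_outlier <- stats::runif(n) < scenario$outlier_prob
  value[is_outlier] <- stats::runif(sum(is_outlier), scenario$outlier_low,
                                    scenario$outlier_high)
  keep <- stats::runif(n) >= scenario$dropout_prob
  if (!any(keep)) {
    stop("degenerate scenario: dropout removed every observation",
         call. = FALSE)
  }
  tibble::tibble(
    site_id = scenario$site_id,
    date = dates[keep],
    value = value[keep]
  )
}

#' Simulate a validation cohort with known construction years
#'
#' Draws `n_sites` change years uniformly over `year_range` (which may start
#' before the reliably observable era, producing a pre-era cohort), assigns
#' each site a change date within its year, simulates each series from the
#' template scenario with a site-specific substream seed, and returns the
#' aligned ground-truth table used to score the estimator.
#'
#' @param n_sites Number of sites (`>= 1`).
#' @param scenario_template A [series_scenario()] whose acquisition and noise
#'   settings are shared by all sites; its `site_id`, `change_date` and `seed`
#'   are overridden per site.
#' @param year_range Length-2 integer vector `c(first, last)` of candidate
#'   construction years.
#' @param seed Master seed; per-site substreams are derived from
#'   `(seed, site_id)` so the collection is reproducible.
#' @return A list with `series` (one tibble, all sites row-bound) and
#'   `truth` (tibble `site_id`, `true_change_year`).
#' @export
simulate_validation_set <- function(n_sites, scenario_template,
                                    year_range, seed = 1L) {
  stopifnot(n_sites >= 1, inherits(scenario_template, "series_scenario"),
            length(year_range) == 2L)
  set.seed(seed)
  pool <- seq(year_range[1], year_range[2])
  years <- pool[sample.int(length(pool), n_sites, replace = TRUE)]
  doy <- sample(32:300, n_sites, replace = TRUE)  # avoid year-boundary ties
  ids <- sprintf("site_%04d", seq_len(n_sites))

  series <- purrr::pmap(
    list(ids, years, doy),
    function(id, yr, d) {
      sc <- scenario_template
      sc$site_id <- id
      sc$change_date <- as.Date(d - 1, origin = as.Date(sprintf("%d-01-01", yr)))
      sc$seed <- site_seed(seed, id)
      simulate_series(sc)
    }
  )
  list(
    series = dplyr::bind_rows(series),
    truth = tibble::tibble(site_id = ids, true_change_year = as.integer(years))
  )
}

#' Simulate a site-and-waterway landscape
#'
#' Places lagoon sites uniformly inside a lon/lat bounding box and scatters
#' simple water features (axis-aligned rectangle polygons and two-vertex
#' polylines) with classes drawn from the hydrography classes the workflow
#' recognises. Polygon areas are computed geodesically on the WGS84
#' ellipsoid; polylines get area 0.
#'
#' @param n_sites,n_features Counts of sites and water features.
#' @param bbox Numeric `c(lon_min, lat_min, lon_max, lat_max)` in WGS84
#'   degrees, non-degenerate.
#' @param seed Integer seed.
#' @param line_fraction Fraction of features generated as polylines.
#' @return A list with `sites` (tibble `site_id`, `lon`, `lat`) and
#'   `features` (tibble `feature_id`, `fclass`, `gtype`, `area_km2`,
#'   `geometry` list-column of lon/lat matrices).
#' @export
simulate_landscape <- function(n_sites, n_features, bbox, seed = 1L,
                               line_fraction = 0.3) {
  stopifnot(length(bbox) == 4L, bbox[1] < bbox[3], bbox[2] < bbox[4])
  set.seed(seed)
  sites <- tibble::tibble(
    site_id = sprintf("site_%04d", seq_len(n_sites)),
    lon = stats::runif(n_sites, bbox[1], bbox[3]),
    lat = stats::runif(n_sites, bbox[2], bbox[4])
  )
  w <- bbox[3] - bbox[1]
  h <- bbox[4] - bbox[2]
  geoms <- vector("list", n_features)
  gtype <- character(n_features)
  for (i in seq_len(n_features)) {
    cx <- stats::runif(1, bbox[1] + 0.1 * w, bbox[3] - 0.1 * w)
    cy <- stats::runif(1, bbox[2] + 0.1 * h, bbox[4] - 0.1 * h)
    if (stats::runif(1) < line_fraction) {
      gtype[i] <- "linestring"
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.02, 0.1) * min(w, h)
      geoms[[i]] <- rbind(
        c(cx - cos(ang) * len, cy - sin(ang) * len),
        c(cx + cos(ang) * len, cy + sin(ang) * len)
      )
    } else {
      gtype[i] <- "polygon"
      dx <- stats::runif(1, 0.01, 0.06) * w / 2
      dy <- stats::runif(1, 0.01, 0.06) * h / 2
      geoms[[i]] <- rbind(
        c(cx - dx, cy - dy), c(cx + dx, cy - dy),
        c(cx + dx, cy + dy), c(cx - dx, cy + dy), c(cx - dx, cy - dy)
      )
    }
  }
  area <- vapply(seq_len(n_features), function(i) {
    if (gtype[i] == "polygon") {
      abs(geosphere::areaPolygon(geoms[[i]])) / 1e6
    } else 0
  }, numeric(1))
  features <- tibble::tibble(
    feature_id = sprintf("feat_%04d", seq_len(n_features)),
    fclass = sample(water_feature_classes(), n_features, replace = TRUE),
    gtype = gtype,
    area_km2 = area,
    geometry = geoms
  )
  list(sites = sites, features = features)
}

#' Hydrography feature classes recognised by the workflow
#'
#' @return Character vector of surface-water classes.
#' @export
water_feature_classes <- function() {
  c("reservoir", "canal/ditch", "lake/pond", "stream/river", "estuary",
    "swamp/marsh")
}
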