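#' Describe a simulated reflectance acquisition scenario
#'
#' A scenario bundles everything needed to simulate one site's near-infrared
#' surface reflectance record: the acquisition window and cadence, the step
#' change from a vegetated mean to a water mean at a known change date, noise,
#' cloud dropout, bright-outlier contamination, and an optional early-record
#' (1984) artifact segment. Reflectance is on the scaled-integer 0--10,000
#' surface reflectance convention.
#'
#' @param site_id Character site identifier.
#' @param record_start,record_end Calendar dates (coerced with [as.Date()])
#'   bounding the acquisition record.
#' @param change_date Calendar date of conversion, or `NA` for a site that
#'   never converts. The first observation dated on or after `change_date`
#'   takes `post_mean` (it models the first image showing water).
#' @param pre_mean,post_mean Segment means in scaled reflectance units.
#' @param noise_sd Additive Gaussian noise standard deviation (reflectance
#'   units, `>= 0`).
#' @param cadence_days Nominal revisit interval in days (integer `>= 1`;
#'   16 for Landsat 5).
#' @param dropout_prob Probability an acquisition is lost (clouds, quality
#'   screening), each observation independently.
#' @param outlier_prob Probability an observation is replaced by a bright
#'   outlier drawn uniformly from `[outlier_low, outlier_high]`.
#' @param outlier_low,outlier_high Bright-outlier range; both must exceed
#'   10,000 so the cleaning rule removes exactly the injected outliers.
#' @param artifact_1984 If `TRUE`, pre-change observations dated in calendar
#'   year 1984 take `artifact_mean` instead of `pre_mean`, emulating artifact
#'   signals in the earliest images of the record.
#' @param artifact_mean Mean used for the 1984 artifact segment.
#' @param seed Integer seed; identical scenarios give identical series.
#'
#' @return A list of class `series_scenario`.
#' @seealso [simulate_series()], [simulate_validation_set()]
#' @export
series_scenario <- function(site_id = "site_1",
                            record_start = "1984-01-01",
                            record_end = "2012-12-31",
                            change_date = "1994-06-01",
                            pre_mean = 3500,
                            post_mean = 800,
                            noise_sd = 300,
                            cadence_days = 16L,
                            dropout_prob = 0.2,
                            outlier_prob = 0.01,
                            outlier_low = 10001,
                            outlier_high = 16000,
                            artifact_1984 = FALSE,
                            artifact_mean = 1200,
                            seed = 1L) {
  record_start <- as.Date(record_start)
  record_end <- as.Date(record_end)
  change_date <- if (is.null(change_date) || is.na(change_date[1])) {
    as.Date(NA)
  } else {
    as.Date(change_date)
  }
  stopifnot(
    is.character(site_id), length(site_id) == 1L,
    !is.na(record_start), !is.na(record_end)
  )
  if (!record_start < record_end) {
    stop("`record_start` must precede `record_end`", call. = FALSE)
  }
  if (!is.na(change_date) &&
      (change_date < record_start || change_date > record_end)) {
    stop("`change_date` must fall within the record window", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cadence_days < 1) stop("`cadence_days` must be >= 1", call. = FALSE)
  for (p in c(dropout_prob, outlier_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (outlier_low <= 10000 || outlier_high <= 10000) {
    stop("outlier bounds must exceed 10,000 (the bright-pixel threshold)",
         call. = FALSE)
  }
  if (outlier_high < outlier_low) {
    stop("`outlier_high` must be >= `outlier_low`", call. = FALSE)
  }
  structure(
    list(
      site_id = site_id, record_start = record_start,
      record_end = record_end, change_date = change_date,
      pre_mean = pre_mean, post_mean = post_mean, noise_sd = noise_sd,
      cadence_days = as.integer(cadence_days), dropout_prob = dropout_prob,
      outlier_prob = outlier_prob, outlier_low = outlier_low,
      outlier_high = outlier_high, artifact_1984 = isTRUE(artifact_1984),
      artifact_mean = artifact_mean, seed = as.integer(seed)
    ),
    class = "series_scenario"
  )
}

#' @export
print.series_scenario <- function(x, ...) {
  cat("<series_scenario> ", x$site_id, ": ",
      format(x$record_start), " .. ", format(x$record_end),
      ", change ", if (is.na(x$change_date)) "none" else format(x$change_date),
      ", step ", x$pre_mean, " -> ", x$post_mean,
      ", noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Convert calendar dates to decimal years
#'
#' Plotting convenience only; all file formats and estimators work on
#' calendar dates.
#'
#' @param dates A `Date` vector.
#' @return Numeric years, `year + (day_of_year - 1) / 365.25`.
#' @export
decimal_year <- function(dates) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  yr + (doy - 1) / 365.25
}

# deterministic per-site substream seed derived from (seed, site_id)
site_seed <- function(seed, site_id) {
  h <- sum(utf8ToInt(site_id) * seq_along(utf8ToInt(site_id)) * 131L)
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483641) + 1L
}
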