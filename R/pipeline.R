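#' Run the end-to-end workflow from files to files
#'
#' Binds all stages: read the series CSV, clean and date every site, and —
#' when the corresponding inputs are given — score against observed years,
#' compute nearest-water distances, cohort summaries, the Mann-Kendall
#' trend on annual median distances, and per-polygon densities. Artifacts
#' are written under `out_dir`; per-stage counts are logged via
#' [message()].
#'
#' @param config A [run_config()].
#' @param paths Named list of input paths: `series` (required),
#'   optionally `truth`, `sites`, `features`, `polygons`, and `out_dir`
#'   (default `"lagoondate_out"`).
#' @return Invisibly, a list with the in-memory results (`estimates`,
#'   and when computed `report`, `distances`, `cohorts`, `trend`,
#'   `density`) plus `counts` and `outputs` (paths written).
#' @export
run_end_to_end <- function(config, paths) {
  stopifnot(inherits(config, "run_config"), !is.null(paths$series))
  out_dir <- paths$out_dir %||% "lagoondate_out"
  for (p in c("series", "truth", "sites", "features", "polygons")) {
    if (!is.null(paths[[p]]) && !file.exists(paths[[p]])) {
      stop("input path does not exist: ", paths[[p]], call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  counts <- list()

  series <- read_series_csv(paths$series)
  counts$sites_read <- length(unique(series$site_id))
  message("read ", counts$sites_read, " site series (",
          nrow(series), " observations)")

  cleaned <- linear_filter(remove_bright(series, config$threshold),
                           config$filter_window)
  counts$observations_cleaned <- nrow(series) - nrow(cleaned)

  estimates <- run_pipeline(cleaned,
                            config = run_config(
                              threshold = config$threshold,
                              filter_window = 1L,  # already filtered above
                              metric = config$metric,
                              era_start = config$era_start,
                              era_end = config$era_end,
                              seed = config$seed))
  counts$sites_estimated <- nrow(estimates)
  counts$sites_skipped <- nrow(attr(estimates, "skipped"))
  message("estimated ", counts$sites_estimated, " sites (",
          counts$sites_skipped, " skipped)")
  est_path <- file.path(out_dir, "estimates.csv")
  write_estimates_csv(estimates, est_path)
  outputs <- c(outputs, est_path)

  result <- list(estimates = estimates)

  if (!is.null(paths$truth)) {
    truth <- read_truth_csv(paths$truth)
    report <- score_validation(estimates, truth,
                               tolerance_years = config$tolerance_years,
                               era_start = config$era_start)
    message(sprintf("validation: %d/%d correct (%.1f%%) at +/-%d year(s)",
                    report$n_correct, report$n_sites,
                    100 * report$accuracy, config$tolerance_years))
    rep_path <- file.path(out_dir, "validation_mismatches.csv")
    readr::write_csv(tidy(report), rep_path)
    outputs <- c(outputs, rep_path)
    result$report <- report
  }

  if (!is.null(paths$sites) && !is.null(paths$features)) {
    sites <- read_geojson(paths$sites, "sites")
    features <- read_geojson(paths$features, "features") %>%
      filter_water_features(config$min_area_km2)
    counts$features_kept <- nrow(features)
    distances <- nearest_water_distance(sites, features)
    dist_path <- file.path(out_dir, "distances.csv")
    readr::write_csv(distances, dist_path)
    outputs <- c(outputs, dist_path)
    result$distances <- distances

    common <- intersect(distances$site_id, estimates$site_id)
    if (length(common) > 0) {
      drec <- dplyr::filter(distances, .data$site_id %in% common)
      eest <- dplyr::filter(estimates, .data$site_id %in% common)
      cohorts <- summarize_by_cohort(drec, eest)
      coh_path <- file.path(out_dir, "cohort_summary.csv")
      readr::write_csv(cohorts, coh_path)
      outputs <- c(outputs, coh_path)
      result$cohorts <- cohorts

      med <- annual_median_distance(drec, eest)
      if (nrow(med) >= 3) {
        trend <- mann_kendall(med$median_m, alpha = config$alpha)
        message("trend on ", nrow(med), " annual medians: ", trend$trend,
                " (p = ", signif(trend$p_value, 3), ")")
        trend_path <- file.path(out_dir, "trend.csv")
        readr::write_csv(tidy(trend), trend_path)
        outputs <- c(outputs, trend_path)
        result$trend <- trend
      }
    }
  }

  if (!is.null(paths$sites) && !is.null(paths$polygons)) {
    sites <- read_geojson(paths$sites, "sites")
    polys <- read_geojson(paths$polygons, "polygons")
    dens <- density_by_polygon(sites, polys)
    dens_path <- file.path(out_dir, "density.csv")
    readr::write_csv(dens, dens_path)
    outputs <- c(outputs, dens_path)
    result$density <- dens
  }

  result$counts <- counts
  result$outputs <- outputs
  invisible(result)
}
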