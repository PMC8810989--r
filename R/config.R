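#' Workflow configuration
#'
#' Bundles every tunable of the dating-and-spatial workflow. Defaults match
#' a Landsat-5-style record: bright-pixel threshold 10,000 on scaled
#' reflectance, 3-observation smoothing window, change-in-mean cost,
#' datable era 1986--2010, +/- 1 year validation tolerance, 0.05 km²
#' hydrography area filter, 5% trend alpha.
#'
#' @param threshold Bright-pixel removal threshold (reflectance).
#' @param filter_window Odd smoothing window (observations); 1 disables.
#' @param metric `"mean"` or `"meanvar"` changepoint cost.
#' @param era_start,era_end Datable era bounds (calendar years).
#' @param tolerance_years Validation tolerance.
#' @param min_area_km2 Minimum hydrography polygon area.
#' @param alpha Mann-Kendall significance level.
#' @param seed Master seed for any simulation performed in the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(threshold = 10000, filter_window = 3L,
                       metric = c("mean", "meanvar"),
                       era_start = 1986, era_end = 2010,
                       tolerance_years = 1L, min_area_km2 = 0.05,
                       alpha = 0.05, seed = 1L) {
  metric <- match.arg(metric)
  filter_window <- as.integer(filter_window)
  stopifnot(
    threshold > 0,
    filter_window >= 1L, filter_window %% 2L == 1L,
    era_start < era_end,
    tolerance_years >= 0,
    min_area_km2 >= 0,
    alpha > 0, alpha < 1
  )
  structure(
    list(threshold = threshold, filter_window = filter_window,
         metric = metric, era_start = era_start, era_end = era_end,
         tolerance_years = as.integer(tolerance_years),
         min_area_km2 = min_area_km2, alpha = alpha,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a flat key-value configuration file
#'
#' YAML with one level of scalar keys; unknown keys are an error so typos
#' don't silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(vals), allowed)
  if (length(extra) > 0) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat("  ", k, ": ", x[[k]], "\n", sep = "")
  invisible(x)
}
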