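#' Remove bright (cloud-contaminated) observations
#'
#' Scaled surface reflectance cannot legitimately exceed 10,000; larger
#' values are caused by bright features such as clouds and are dropped
#' before changepoint detection. The comparison is strict: a value of
#' exactly `threshold` is retained.
#'
#' @param series Tibble with columns `site_id`, `date`, `value` (one or
#'   several sites).
#' @param threshold Reflectance cutoff, default 10,000.
#' @return The series with rows `value > threshold` removed, order
#'   preserved. Errors if cleaning empties any site's record.
#' @export
remove_bright <- function(series, threshold = 10000) {
  series <- validate_series(series)
  out <- dplyr::filter(series, .data$value <= threshold)
  gone <- setdiff(unique(series$site_id), unique(out$site_id))
  if (length(gone) > 0) {
    stop("unusable site: cleaning removed every observation for ",
         paste(gone, collapse = ", "), call. = FALSE)
  }
  out
}

#' Smooth a reflectance series with a centred moving average
#'
#' Linear filtering step applied after bright-pixel removal to reduce
#' residual noise. The filter is a centred moving average over `window`
#' consecutive observations (observation index, not calendar time, since
#' acquisitions are irregular after cloud screening); at the record edges
#' the window truncates to the available observations. `window = 1`
#' disables smoothing.
#'
#' @param series Tibble with `site_id`, `date`, `value`.
#' @param window Odd integer `>= 1`, default 3.
#' @return The series with smoothed `value`; dates and length unchanged.
#' @export
linear_filter <- function(series, window = 3L) {
  series <- validate_series(series)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  series %>%
    dplyr::group_by(.data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (window > n) {
        stop("filter window (", window, ") exceeds series length (", n,
             ") for site ", key$site_id, call. = FALSE)
      }
      h <- (window - 1L) %/% 2L
      cs <- cumsum(c(0, df$value))
      i <- seq_len(n)
      lo <- pmax(1L, i - h)
      hi <- pmin(n, i + h)
      df$value <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      df
    }) %>%
    dplyr::ungroup()
}

validate_series <- function(series) {
  if (!all(c("site_id", "date", "value") %in% names(series))) {
    stop("series must have columns site_id, date, value", call. = FALSE)
  }
  if (any(!is.finite(series$value))) {
    stop("series values must be finite", call. = FALSE)
  }
  bad <- series %>%
    dplyr::group_by(.data$site_id) %>%
    dplyr::summarise(ok = !is.unsorted(.data$date, strictly = TRUE)) %>%
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("dates must be strictly increasing within a site: ",
         paste(bad$site_id, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(series)
}
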