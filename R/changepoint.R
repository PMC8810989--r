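#' Detect the single best changepoint under a normal likelihood
#'
#' Splits a series into two homogeneous segments S1 (up to and including
#' `tau`) and S2 (the rest) at the split minimising the total cost, the
#' at-most-one-change reduction of binary segmentation when exactly one
#' changepoint is allowed. Two costs are available:
#'
#' * `"mean"` — change in mean: the cost of a segment is its sum of squared
#'   deviations from the segment mean (normal likelihood, common variance).
#' * `"meanvar"` — change in mean and variance: a segment of length
#'   \eqn{n_k} with maximum-likelihood variance \eqn{\hat\sigma^2_k} costs
#'   \eqn{n_k \log \max(\hat\sigma^2_k, \epsilon)}, with a small variance
#'   floor \eqn{\epsilon} guarding `log(0)` on flat segments.
#'
#' Each segment must contain at least `min_seg` observations (1 for
#' `"mean"`, 2 for `"meanvar"` by default, so segment variances are
#' defined). Cost ties are broken toward the smallest `tau`. A fit is
#' flagged degenerate when the two segment means differ by less than
#' `mean_floor` (no meaningful change) or, under `"meanvar"`, when a
#' segment variance hit the floor.
#'
#' @param series Tibble with `site_id`, `date`, `value` for a single site.
#' @param metric `"mean"` (default) or `"meanvar"`.
#' @param min_seg Minimum segment length; defaults to 1 (`"mean"`) or 2
#'   (`"meanvar"`).
#' @param var_floor Variance floor \eqn{\epsilon} for `"meanvar"`,
#'   default `1e-8` (squared reflectance units).
#' @param mean_floor Minimum |mean(S1) - mean(S2)| regarded as a real
#'   change, default `1e-8`.
#' @return An object of class `changepoint_fit`: a list with `site_id`,
#'   `tau` (0-based index of the last observation of S1), `changepoint_date`
#'   (date of the first observation of S2), `s1_mean`, `s2_mean`, `s1_var`,
#'   `s2_var` (maximum-likelihood variances), `cost`, `metric`, `n`,
#'   `degenerate`, and the input `series`. Use [tidy()] for a one-row
#'   tibble.
#' @examples
#' s <- tibble::tibble(site_id = "a",
#'                     date = as.Date("1990-01-01") + 16 * 0:5,
#'                     value = c(10, 10, 10, 2, 2, 2))
#' detect_single_changepoint(s)
#' @export
detect_single_changepoint <- function(series,
                                      metric = c("mean", "meanvar"),
                                      min_seg = NULL,
                                      var_floor = 1e-8,
                                      mean_floor = 1e-8) {
  metric <- match.arg(metric)
  series <- validate_series(series)
  if (length(unique(series$site_id)) != 1L) {
    stop("detect_single_changepoint() expects a single site", call. = FALSE)
  }
  x <- series$value
  n <- length(x)
  if (is.null(min_seg)) min_seg <- if (metric == "mean") 1L else 2L
  if (n < 2L * min_seg) {
    stop("series too short: need at least ", 2L * min_seg,
         " observations for metric '", metric, "'", call. = FALSE)
  }

  n1 <- seq.int(min_seg, n - min_seg)     # candidate sizes of S1
  s <- cumsum(x)
  ss <- cumsum(x^2)
  s1 <- s[n1];  ss1 <- ss[n1]
  s2 <- s[n] - s1; ss2 <- ss[n] - ss1
  n2 <- n - n1

  if (metric == "mean") {
    cost <- (ss1 - s1^2 / n1) + (ss2 - s2^2 / n2)
  } else {
    v1 <- pmax(ss1 / n1 - (s1 / n1)^2, var_floor)
    v2 <- pmax(ss2 / n2 - (s2 / n2)^2, var_floor)
    cost <- n1 * log(v1) + n2 * log(v2)
  }
  k <- which.min(cost)                    # ties -> smallest tau
  n1k <- n1[k]
  x1 <- x[seq_len(n1k)]
  x2 <- x[(n1k + 1L):n]
  v1k <- mean(x1^2) - mean(x1)^2
  v2k <- mean(x2^2) - mean(x2)^2
  degen <- abs(mean(x1) - mean(x2)) < mean_floor ||
    (metric == "meanvar" && (v1k < var_floor || v2k < var_floor))

  structure(
    list(
      site_id = series$site_id[1],
      tau = n1k - 1L,
      changepoint_date = series$date[n1k + 1L],
      s1_mean = mean(x1), s2_mean = mean(x2),
      s1_var = v1k, s2_var = v2k,
      cost = cost[k], metric = metric, n = n,
      degenerate = degen,
      series = series
    ),
    class = "changepoint_fit"
  )
}

#' Segment costs at a given split
#'
#' Exposes the cost decomposition used by [detect_single_changepoint()]:
#' for a split after 0-based index `tau`, returns the cost of each segment
#' under the chosen metric.
#'
#' @inheritParams detect_single_changepoint
#' @param tau 0-based index of the last observation of S1.
#' @return Named numeric vector `c(cost_s1, cost_s2)`.
#' @export
segment_costs <- function(series, tau, metric = c("mean", "meanvar"),
                          min_seg = NULL, var_floor = 1e-8) {
  metric <- match.arg(metric)
  series <- validate_series(series)
  x <- series$value
  n <- length(x)
  if (is.null(min_seg)) min_seg <- if (metric == "mean") 1L else 2L
  n1 <- tau + 1L
  if (n1 < min_seg || n1 > n - min_seg) {
    stop("inadmissible tau = ", tau, " for n = ", n, ", min_seg = ", min_seg,
         call. = FALSE)
  }
  seg_cost <- function(xk) {
    if (metric == "mean") {
      sum((xk - mean(xk))^2)
    } else {
      length(xk) * log(max(mean(xk^2) - mean(xk)^2, var_floor))
    }
  }
  c(cost_s1 = seg_cost(x[seq_len(n1)]), cost_s2 = seg_cost(x[(n1 + 1L):n]))
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat("<changepoint_fit> site ", x$site_id, " (", x$metric, ", n = ", x$n,
      ")\n  tau = ", x$tau, " -> ", format(x$changepoint_date),
      "\n  S1 mean ", signif(x$s1_mean, 5), ", S2 mean ",
      signif(x$s2_mean, 5), ", cost ", signif(x$cost, 6),
      if (x$degenerate) "  [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a changepoint fit
#'
#' @param x A `changepoint_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the fitted split, segment statistics,
#'   cost, metric and degeneracy flag.
#' @method tidy changepoint_fit
#' @export
tidy.changepoint_fit <- function(x, ...) {
  tibble::tibble(
    site_id = x$site_id, tau = x$tau,
    changepoint_date = x$changepoint_date,
    s1_mean = x$s1_mean, s2_mean = x$s2_mean,
    s1_var = x$s1_var, s2_var = x$s2_var,
    cost = x$cost, metric = x$metric, degenerate = x$degenerate
  )
}

#' @rdname tidy.changepoint_fit
#' @return `glance()`: a one-row tibble with `n`, `cost`, `metric`,
#'   `degenerate`.
#' @method glance changepoint_fit
#' @export
glance.changepoint_fit <- function(x, ...) {
  tibble::tibble(n = x$n, cost = x$cost, metric = x$metric,
                 degenerate = x$degenerate)
}

#' Plot a fitted changepoint over its series
#'
#' @param object A `changepoint_fit`.
#' @param ... Unused.
#' @return A ggplot: observations, per-segment mean lines, and a vertical
#'   line at the changepoint date.
#' @method autoplot changepoint_fit
#' @export
autoplot.changepoint_fit <- function(object, ...) {
  df <- object$series
  seg <- tibble::tibble(
    xmin = c(min(df$date), object$changepoint_date),
    xmax = c(df$date[object$tau + 1L], max(df$date)),
    y = c(object$s1_mean, object$s2_mean)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                   y = .data$y, yend = .data$y),
      colour = "firebrick", linewidth = 1
    ) +
    ggplot2::geom_vline(xintercept = object$changepoint_date,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "surface reflectance (scaled)",
                  title = paste0(object$site_id, ": changepoint ",
                                 format(object$changepoint_date))) +
    ggplot2::theme_minimal()
}
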