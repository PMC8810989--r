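#' Area-filter hydrography features
#'
#' Small hydrography polygons are frequently misclassified (non-water
#' features coded as water), so polygons below a minimum area are dropped
#' before distance analysis. The comparison is strict: a polygon of exactly
#' `min_area_km2` is retained. Polylines carry no area and are always
#' retained.
#'
#' @param features Feature tibble (`feature_id`, `fclass`, `gtype`,
#'   `area_km2`, `geometry`), e.g. from [simulate_landscape()] or
#'   [read_geojson()].
#' @param min_area_km2 Minimum polygon area, default 0.05 km².
#' @return The filtered feature tibble.
#' @export
filter_water_features <- function(features, min_area_km2 = 0.05) {
  dplyr::filter(features,
                .data$gtype != "polygon" | .data$area_km2 >= min_area_km2)
}

#' Geodesic nearest-water distance per site
#'
#' For each site, computes the geodesic (WGS84 ellipsoid) distance to the
#' nearest point of each water feature and keeps the closest feature. A
#' site inside a polygon is at distance 0. Feature boundaries are densified
#' to at most `densify_m` metres between candidate points and the distance
#' is then refined by a one-dimensional minimisation of the ellipsoidal
#' distance along the best candidate chord, so the point-to-segment
#' approximation error stays well under a metre.
#'
#' @param sites Tibble `site_id`, `lon`, `lat` (WGS84 degrees).
#' @param features Feature tibble as in [filter_water_features()];
#'   must be non-empty.
#' @param densify_m Maximum candidate spacing along boundaries, metres.
#' @return Tibble `site_id`, `feature_id`, `fclass`, `distance_m`, one row
#'   per site (its nearest feature).
#' @export
nearest_water_distance <- function(sites, features, densify_m = 500) {
  if (nrow(features) == 0) {
    stop("empty feature set: no water features to measure against",
         call. = FALSE)
  }
  purrr::pmap(sites, function(site_id, lon, lat, ...) {
    p <- c(lon, lat)
    d <- vapply(seq_len(nrow(features)), function(i) {
      point_feature_distance(p, features$geometry[[i]],
                             features$gtype[i], densify_m)
    }, numeric(1))
    k <- which.min(d)
    tibble::tibble(site_id = site_id,
                   feature_id = features$feature_id[k],
                   fclass = features$fclass[k],
                   distance_m = d[k])
  }) %>% dplyr::bind_rows()
}

# geodesic distance from point p (lon, lat) to one feature geometry
point_feature_distance <- function(p, coords, gtype, densify_m) {
  if (gtype == "polygon" &&
      sp::point.in.polygon(p[1], p[2], coords[, 1], coords[, 2]) > 0) {
    return(0)
  }
  nseg <- nrow(coords) - 1L
  best <- Inf
  for (i in seq_len(nseg)) {
    a <- coords[i, ]
    b <- coords[i + 1L, ]
    best <- min(best, point_segment_distance(p, a, b, densify_m))
  }
  best
}

# distance from p to the lon/lat chord a-b: densified scan + golden-section
# refinement of the ellipsoidal distance along the chord parameter
point_segment_distance <- function(p, a, b, densify_m) {
  seg_len <- geosphere::distGeo(a, b)
  if (seg_len == 0) return(geosphere::distGeo(p, a))
  m <- max(2L, ceiling(seg_len / densify_m) + 1L)
  t <- seq(0, 1, length.out = m)
  pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  d <- geosphere::distGeo(rbind(p), pts)
  k <- which.min(d)
  lo <- t[max(1L, k - 1L)]
  hi <- t[min(m, k + 1L)]
  f <- function(tt) {
    geosphere::distGeo(p, c(a[1] + tt * (b[1] - a[1]),
                            a[2] + tt * (b[2] - a[2])))
  }
  stats::optimize(f, c(lo, hi), tol = 1e-10)$objective
}

#' Summarise nearest-water distances by construction cohort
#'
#' Bins sites into construction cohorts from their estimates (pre-era sites
#' form the earliest cohort) and reports the mean and median nearest-water
#' distance per cohort, both over all waterways and per feature class.
#' Cohort-by-class cells with no site are absent from the output (no
#' zero-filling), mirroring the convention that a class simply was not the
#' closest waterway for that period.
#'
#' @param records Distance records from [nearest_water_distance()].
#' @param estimates Estimates from [run_pipeline()].
#' @param cohort_breaks Increasing integer years; cohort k spans
#'   `[breaks[k], breaks[k+1] - 1]`, with open cohorts below and above.
#'   Defaults to the 1987--1998 two-year bins used for lagoon analyses.
#' @return Tibble `cohort`, `fclass` (including `"all"`), `mean_m`,
#'   `median_m`, `n`, ordered by cohort.
#' @export
summarize_by_cohort <- function(records, estimates,
                                cohort_breaks = c(1987, 1990, 1992,
                                                  1994, 1996, 1998)) {
  stopifnot(!is.unsorted(cohort_breaks, strictly = TRUE))
  joined <- dplyr::inner_join(records, estimates, by = "site_id")
  if (nrow(joined) != nrow(records)) {
    stop("every distance record needs a construction estimate", call. = FALSE)
  }
  labs <- cohort_labels(cohort_breaks)
  joined$cohort <- cohort_of(
    ifelse(joined$kind == "PRE_ERA", cohort_breaks[1] - 1L, joined$year),
    cohort_breaks, labs)
  per_class <- joined %>%
    dplyr::group_by(.data$cohort, .data$fclass) %>%
    dplyr::summarise(mean_m = mean(.data$distance_m),
                     median_m = stats::median(.data$distance_m),
                     n = dplyr::n(), .groups = "drop")
  overall <- joined %>%
    dplyr::group_by(.data$cohort) %>%
    dplyr::summarise(fclass = "all", mean_m = mean(.data$distance_m),
                     median_m = stats::median(.data$distance_m),
                     n = dplyr::n(), .groups = "drop")
  dplyr::bind_rows(overall, per_class) %>%
    dplyr::arrange(factor(.data$cohort, levels = labs), .data$fclass)
}

cohort_labels <- function(breaks) {
  k <- length(breaks)
  inner <- vapply(seq_len(k - 1L), function(i) {
    if (breaks[i + 1L] - breaks[i] == 1L) as.character(breaks[i])
    else paste0(breaks[i], "-", breaks[i + 1L] - 1L)
  }, character(1))
  c(paste0("<", breaks[1]), inner, paste0(">=", breaks[k]))
}

cohort_of <- function(years, breaks, labs) {
  idx <- findInterval(years, breaks) + 1L
  labs[idx]
}

#' Mann-Kendall monotonic trend test
#'
#' Nonparametric test for a monotonic trend in an ordered series, based on
#' the sign statistic \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)}. The
#' variance of S uses the tie correction
#' \eqn{\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18} (sum over
#' tie groups of size t), and the standard normal deviate applies a
#' continuity correction: \eqn{Z = (S-1)/\sqrt{\mathrm{var}(S)}} for
#' \eqn{S>0}, 0 for \eqn{S=0}, \eqn{(S+1)/\sqrt{\mathrm{var}(S)}} for
#' \eqn{S<0}. The two-sided p-value comes from the normal approximation;
#' for small n its accuracy against the exact permutation null is
#' documented in the package vignette.
#'
#' @param values Ordered numeric series (e.g. annual median distances),
#'   `n >= 3`.
#' @param alpha Significance level for the trend call, default 0.05.
#' @return Object of class `mann_kendall`: list with `S`, `var_S`, `Z`,
#'   `tau` (S over the number of pairs), `p_value`, `trend`
#'   (`"INCREASING"`, `"DECREASING"` or `"NONE"`), `alpha`, `n`,
#'   `degenerate` (all values tied).
#' @examples
#' mann_kendall(c(1, 3, 2, 5, 6, 8))
#' @export
mann_kendall <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  S <- 0
  for (i in seq_len(n - 1L)) {
    S <- S + sum(sign(values[(i + 1L):n] - values[i]))
  }
  ties <- table(values)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  degenerate <- var_S == 0
  Z <- if (degenerate || S == 0) 0
  else if (S > 0) (S - 1) / sqrt(var_S)
  else (S + 1) / sqrt(var_S)
  p <- if (degenerate || S == 0) 1 else 2 * stats::pnorm(-abs(Z))
  trend <- if (!degenerate && p < alpha) {
    if (S > 0) "INCREASING" else "DECREASING"
  } else "NONE"
  structure(
    list(S = as.integer(S), var_S = var_S, Z = Z,
         tau = S / (n * (n - 1) / 2), p_value = p, trend = trend,
         alpha = alpha, n = n, degenerate = degenerate),
    class = "mann_kendall"
  )
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat("<mann_kendall> n = ", x$n, ", S = ", x$S,
      ", tau = ", signif(x$tau, 3), ", Z = ", signif(x$Z, 4),
      ", p = ", signif(x$p_value, 3), " -> ", x$trend,
      if (x$degenerate) " [degenerate: all tied]" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a Mann-Kendall result
#'
#' @param x A `mann_kendall` object.
#' @param ... Unused.
#' @return One-row tibble with `S`, `var_S`, `Z`, `tau`, `p_value`,
#'   `trend`.
#' @method tidy mann_kendall
#' @export
tidy.mann_kendall <- function(x, ...) {
  tibble::tibble(S = x$S, var_S = x$var_S, Z = x$Z, tau = x$tau,
                 p_value = x$p_value, trend = x$trend)
}

#' @rdname tidy.mann_kendall
#' @method glance mann_kendall
#' @export
glance.mann_kendall <- function(x, ...) {
  tibble::tibble(n = x$n, alpha = x$alpha, degenerate = x$degenerate,
                 trend = x$trend)
}

#' Lagoon density per polygon
#'
#' Counts sites inside each polygon (point-in-polygon on lon/lat; a site on
#' a shared boundary is assigned to the first containing polygon in stable
#' `polygon_id` order) and reports density per `per_area_km2` of geodesic
#' polygon area.
#'
#' @param sites Tibble `site_id`, `lon`, `lat`.
#' @param polygons Tibble `polygon_id`, `geometry` (closed lon/lat ring
#'   matrices), optional `area_km2` (computed geodesically when absent).
#' @param per_area_km2 Reporting area unit, default 100 km².
#' @return Tibble `polygon_id`, `area_km2`, `count`, `density`, with
#'   attribute `unassigned`: site_ids falling in no polygon.
#' @export
density_by_polygon <- function(sites, polygons, per_area_km2 = 100) {
  polygons <- dplyr::arrange(polygons, .data$polygon_id)
  if (!"area_km2" %in% names(polygons) || anyNA(polygons$area_km2)) {
    polygons$area_km2 <- vapply(polygons$geometry, function(g) {
      abs(geosphere::areaPolygon(g)) / 1e6
    }, numeric(1))
  }
  if (any(polygons$area_km2 <= 0)) {
    stop("zero-area polygon: ",
         paste(polygons$polygon_id[polygons$area_km2 <= 0], collapse = ", "),
         call. = FALSE)
  }
  assigned <- rep(NA_character_, nrow(sites))
  for (j in seq_len(nrow(polygons))) {
    g <- polygons$geometry[[j]]
    inside <- sp::point.in.polygon(sites$lon, sites$lat, g[, 1], g[, 2]) > 0
    take <- inside & is.na(assigned)
    assigned[take] <- polygons$polygon_id[j]
  }
  counts <- table(factor(assigned, levels = polygons$polygon_id))
  out <- tibble::tibble(
    polygon_id = polygons$polygon_id,
    area_km2 = polygons$area_km2,
    count = as.integer(counts),
    density = as.integer(counts) / polygons$area_km2 * per_area_km2
  )
  attr(out, "unassigned") <- sites$site_id[is.na(assigned)]
  out
}

#' Annual medians of nearest-water distances
#'
#' Convenience for the trend stage: joins distance records to estimates,
#' keeps dated (`YEAR`) sites, and returns one median distance per
#' construction year, ordered by year.
#'
#' @inheritParams summarize_by_cohort
#' @return Tibble `year`, `median_m`, `n`.
#' @export
annual_median_distance <- function(records, estimates) {
  dplyr::inner_join(records, estimates, by = "site_id") %>%
    dplyr::filter(.data$kind == "YEAR") %>%
    dplyr::group_by(year = .data$year) %>%
    dplyr::summarise(median_m = stats::median(.data$distance_m),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$year)
}

#' Plot nearest-water distances by feature class
#'
#' @param records Tibble from [nearest_water_distance()].
#' @return A ggplot boxplot of distance by nearest-feature class.
#' @export
plot_nearest_distances <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$fclass, y = .data$distance_m)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "distance to nearest water feature (m)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
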