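#' Read a reflectance series CSV
#'
#' Expects header `site_id,date,value` with ISO-8601 dates. Rows are grouped
#' by site and sorted by date; malformed rows are reported with their line
#' numbers, and duplicate (site, date) rows are an error.
#'
#' @param path CSV file path.
#' @return Series tibble `site_id`, `date` (Date), `value`.
#' @export
read_series_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    date = readr::col_date(),
    value = readr::col_double()
  ))
  if (!identical(names(df), c("site_id", "date", "value"))) {
    stop("expected header site_id,date,value in ", path, call. = FALSE)
  }
  bad <- which(is.na(df$date) | is.na(df$value) | is.na(df$site_id))
  if (length(bad) > 0) {
    stop("unparseable rows in ", path, " at data line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[c("site_id", "date")])
  if (any(dup)) {
    stop("duplicate (site_id, date) rows in ", path, " at data line(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(df, .data$site_id, .data$date)
}

#' Write a reflectance series CSV
#'
#' @param series Series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  readr::write_csv(series[c("site_id", "date", "value")], path)
  invisible(path)
}

#' Read / write small tabular artifacts
#'
#' `read_truth_csv()` reads `site_id,true_change_year`;
#' `read_estimates_csv()` and `write_estimates_csv()` round-trip the
#' estimate table (`site_id,kind,year,flag`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_truth_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    true_change_year = readr::col_integer()
  ))
}

#' @rdname read_truth_csv
#' @export
read_estimates_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    kind = readr::col_character(),
    year = readr::col_integer(),
    flag = readr::col_character()
  ))
}

#' @rdname read_truth_csv
#' @param estimates Estimate tibble.
#' @export
write_estimates_csv <- function(estimates, path) {
  readr::write_csv(estimates, path)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' Minimal reader for the package's GeoJSON contract (WGS84 lon/lat):
#' `kind = "sites"` expects Point features with a `site_id` property;
#' `kind = "features"` expects Polygon/LineString features with `fclass`
#' and `area_km2` properties; `kind = "polygons"` expects Polygon features
#' with a `polygon_id` property (exterior ring only; `area_km2` optional).
#' Polygon rings must be closed and free of self-intersections.
#'
#' @param path GeoJSON file path.
#' @param kind One of `"sites"`, `"features"`, `"polygons"`.
#' @return A typed tibble matching [simulate_landscape()] output.
#' @export
read_geojson <- function(path, kind = c("sites", "features", "polygons")) {
  kind <- match.arg(kind)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  }
  feats <- gj$features
  get_id <- function(f, key, i) {
    id <- f$properties[[key]]
    if (is.null(id)) stop("feature ", i, " in ", path, " missing required ",
                          "property '", key, "'", call. = FALSE)
    as.character(id)
  }
  if (kind == "sites") {
    rows <- purrr::imap(feats, function(f, i) {
      if (!identical(f$geometry$type, "Point")) {
        stop("site features must be Points (feature ", i, ")", call. = FALSE)
      }
      cc <- unlist(f$geometry$coordinates)
      tibble::tibble(site_id = get_id(f, "site_id", i),
                     lon = cc[1], lat = cc[2])
    })
    out <- dplyr::bind_rows(rows)
    if (any(abs(out$lon) > 180 | abs(out$lat) > 90)) {
      stop("site coordinates outside WGS84 lon/lat range", call. = FALSE)
    }
    return(out)
  }
  parse_geom <- function(f, i, id) {
    gt <- f$geometry$type
    if (gt == "Polygon") {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                    function(p) unlist(p)[1:2]))
      check_ring(ring, id)
      list(gtype = "polygon", coords = ring)
    } else if (gt == "LineString") {
      list(gtype = "linestring",
           coords = do.call(rbind, lapply(f$geometry$coordinates,
                                          function(p) unlist(p)[1:2])))
    } else {
      stop("unsupported geometry '", gt, "' for feature ", id, call. = FALSE)
    }
  }
  if (kind == "features") {
    rows <- purrr::imap(feats, function(f, i) {
      id <- get_id(f, "feature_id", i)
      fclass <- get_id(f, "fclass", i)
      if (is.null(f$properties$area_km2)) {
        stop("feature ", id, " missing required property 'area_km2'",
             call. = FALSE)
      }
      g <- parse_geom(f, i, id)
      tibble::tibble(feature_id = id, fclass = fclass, gtype = g$gtype,
                     area_km2 = as.numeric(f$properties$area_km2),
                     geometry = list(g$coords))
    })
    return(dplyr::bind_rows(rows))
  }
  rows <- purrr::imap(feats, function(f, i) {
    id <- get_id(f, "polygon_id", i)
    g <- parse_geom(f, i, id)
    if (g$gtype != "polygon") {
      stop("watershed features must be Polygons (", id, ")", call. = FALSE)
    }
    a <- f$properties$area_km2
    tibble::tibble(polygon_id = id,
                   area_km2 = if (is.null(a)) NA_real_ else as.numeric(a),
                   geometry = list(g$coords))
  })
  dplyr::bind_rows(rows)
}

# ring closure + simple (non-self-intersecting) check, O(n^2) segment pairs
check_ring <- function(ring, id) {
  n <- nrow(ring)
  if (n < 4 || any(ring[1, ] != ring[n, ])) {
    stop("polygon ", id, " ring is not closed", call. = FALSE)
  }
  segs <- lapply(seq_len(n - 1L), function(i) rbind(ring[i, ], ring[i + 1L, ]))
  for (i in seq_along(segs)) {
    for (j in seq_along(segs)) {
      if (j <= i + 1L) next
      if (i == 1L && j == length(segs)) next  # closing segment adjacency
      if (segments_cross(segs[[i]], segs[[j]])) {
        stop("polygon ", id, " is invalid: self-intersecting ring",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

segments_cross <- function(s1, s2) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(s2[1, ], s2[2, ], s1[1, ])
  d2 <- d(s2[1, ], s2[2, ], s1[2, ])
  d3 <- d(s1[1, ], s1[2, ], s2[1, ])
  d4 <- d(s1[1, ], s1[2, ], s2[2, ])
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Write site / feature / polygon tables as GeoJSON
#'
#' Inverse of [read_geojson()]; writes a WGS84 FeatureCollection.
#'
#' @param x A sites, features, or polygons tibble.
#' @param path Output path.
#' @param kind One of `"sites"`, `"features"`, `"polygons"`.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path, kind = c("sites", "features", "polygons")) {
  kind <- match.arg(kind)
  coords_list <- function(m) unname(lapply(seq_len(nrow(m)),
                                           function(i) as.numeric(m[i, ])))
  feats <- switch(kind,
    sites = purrr::pmap(x, function(site_id, lon, lat, ...) {
      list(type = "Feature",
           properties = list(site_id = site_id),
           geometry = list(type = "Point",
                           coordinates = c(lon, lat)))
    }),
    features = purrr::pmap(x, function(feature_id, fclass, gtype, area_km2,
                                       geometry, ...) {
      geom <- if (gtype == "polygon") {
        list(type = "Polygon", coordinates = list(coords_list(geometry)))
      } else {
        list(type = "LineString", coordinates = coords_list(geometry))
      }
      list(type = "Feature",
           properties = list(feature_id = feature_id, fclass = fclass,
                             area_km2 = area_km2),
           geometry = geom)
    }),
    polygons = purrr::pmap(x, function(polygon_id, geometry, ...) {
      props <- list(polygon_id = polygon_id)
      extra <- list(...)
      if (!is.null(extra$area_km2) && !is.na(extra$area_km2)) {
        props$area_km2 <- extra$area_km2
      }
      list(type = "Feature", properties = props,
           geometry = list(type = "Polygon",
                           coordinates = list(coords_list(geometry))))
    })
  )
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
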