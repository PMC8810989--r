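rect <- function(lon0, lat0, lon1, lat1) {
  rbind(c(lon0, lat0), c(lon1, lat0), c(lon1, lat1), c(lon0, lat1),
        c(lon0, lat0))
}

feat_tbl <- function(..., fclass = "lake/pond") {
  geoms <- list(...)
  tibble::tibble(
    feature_id = sprintf("f%d", seq_along(geoms)),
    fclass = rep_len(fclass, length(geoms)),
    gtype = vapply(geoms, function(g) {
      if (nrow(g) > 2 && all(g[1, ] == g[nrow(g), ])) "polygon"
      else "linestring"
    }, character(1)),
    area_km2 = vapply(geoms, function(g) {
      if (nrow(g) > 2 && all(g[1, ] == g[nrow(g), ]))
        abs(geosphere::areaPolygon(g)) / 1e6 else 0
    }, numeric(1)),
    geometry = geoms
  )
}

test_that("area filter drops small polygons but never polylines", {
  small <- rect(-78, 35, -78 + 0.002, 35 + 0.002)    # ~0.04 km2
  big <- rect(-78.5, 35, -78.5 + 0.01, 35 + 0.01)
  line <- rbind(c(-78.2, 35.0), c(-78.2, 35.1))
  ft <- feat_tbl(small, big, line)
  kept <- filter_water_features(ft)
  expect_lt(ft$area_km2[1], 0.05)
  expect_equal(kept$feature_id, c("f2", "f3"))

  # exactly at the cutoff is retained ("less than" is strict)
  exact <- ft[2, ]
  exact$area_km2 <- 0.05
  expect_equal(nrow(filter_water_features(exact)), 1)
  expect_equal(nrow(filter_water_features(ft[0, ])), 0)
})

test_that("nearest distance: vertex, containment, and empty-set error", {
  r <- rect(-78.1, 35.1, -78.0, 35.2)
  ft <- feat_tbl(r)
  on_vertex <- tibble::tibble(site_id = "v", lon = -78.1, lat = 35.1)
  inside <- tibble::tibble(site_id = "i", lon = -78.05, lat = 35.15)
  expect_equal(nearest_water_distance(on_vertex, ft)$distance_m, 0)
  expect_equal(nearest_water_distance(inside, ft)$distance_m, 0)
  expect_error(nearest_water_distance(inside, ft[0, ]), "empty feature set")
})

test_that("site off a rectangle edge matches a direct ellipsoidal solve", {
  r <- rect(-78.1, 35.1, -78.0, 35.2)
  ft <- feat_tbl(r)
  # due south of the bottom edge: nearest boundary point shares the meridian
  site <- tibble::tibble(site_id = "s", lon = -78.05, lat = 35.05)
  got <- nearest_water_distance(site, ft)$distance_m
  oracle <- geosphere::distGeo(c(-78.05, 35.05), c(-78.05, 35.1))
  expect_lt(abs(got - oracle), 1)

  # off the corner: nearest boundary point is the corner itself
  corner_site <- tibble::tibble(site_id = "c", lon = -78.15, lat = 35.05)
  got2 <- nearest_water_distance(corner_site, ft)$distance_m
  oracle2 <- geosphere::distGeo(c(-78.15, 35.05), c(-78.1, 35.1))
  expect_lt(abs(got2 - oracle2), 1)
})

test_that("halving the densification step moves distances by < 1 m", {
  set.seed(13)
  ls <- simulate_landscape(15, 8, c(-78.5, 34.5, -77.5, 35.5), seed = 13L)
  d1 <- nearest_water_distance(ls$sites, ls$features, densify_m = 500)
  d2 <- nearest_water_distance(ls$sites, ls$features, densify_m = 250)
  expect_lt(max(abs(d1$distance_m - d2$distance_m)), 1)
})

test_that("adding features can only decrease the minimum distance", {
  set.seed(14)
  ls <- simulate_landscape(10, 6, c(-78.5, 34.5, -77.5, 35.5), seed = 14L)
  d_few <- nearest_water_distance(ls$sites, ls$features[1:3, ])
  d_all <- nearest_water_distance(ls$sites, ls$features)
  expect_true(all(d_all$distance_m <= d_few$distance_m + 1e-9))
  expect_true(all(d_all$distance_m >= 0))
})

test_that("cohort summary reproduces hand-computed cells and conserves n", {
  recs <- tibble::tibble(
    site_id = c("a", "b", "c", "d", "e"),
    feature_id = "f1",
    fclass = c("stream/river", "stream/river", "stream/river",
               "canal/ditch", "stream/river"),
    distance_m = c(100, 200, 300, 50, 400))
  est <- tibble::tibble(
    site_id = c("a", "b", "c", "d", "e"),
    kind = c("YEAR", "YEAR", "YEAR", "PRE_ERA", "YEAR"),
    year = c(1988L, 1988L, 1989L, NA, 1994L),
    flag = NA_character_)
  tab <- summarize_by_cohort(recs, est)
  all8789 <- tab[tab$cohort == "1987-1989" & tab$fclass == "all", ]
  expect_equal(all8789$mean_m, 200)
  expect_equal(all8789$median_m, 200)
  expect_equal(all8789$n, 3)
  pre <- tab[tab$cohort == "<1987" & tab$fclass == "all", ]
  expect_equal(pre$mean_m, 50)
  # no reservoir rows at all: absent, not zero-filled
  expect_false("reservoir" %in% tab$fclass)
  # record conservation across cohorts
  expect_equal(sum(tab$n[tab$fclass == "all"]), nrow(recs))
  # single record cohort: mean = median
  single <- tab[tab$cohort == "1994-1995" & tab$fclass == "all", ]
  expect_equal(single$mean_m, single$median_m)
})

test_that("density scales with count and inversely with area", {
  # ~0.09 deg x 0.09 deg rectangle; compute its geodesic area for the check
  p1 <- rect(-78.1, 35.1, -78.0, 35.2)
  polys <- tibble::tibble(polygon_id = "w1", geometry = list(p1))
  a1 <- abs(geosphere::areaPolygon(p1)) / 1e6
  one <- tibble::tibble(site_id = "s1", lon = -78.05, lat = 35.15)
  d <- density_by_polygon(one, polys)
  expect_equal(d$count, 1L)
  expect_equal(d$density, 1 / a1 * 100)
  two <- dplyr::bind_rows(one, tibble::tibble(site_id = "s2", lon = -78.04,
                                              lat = 35.16))
  d2 <- density_by_polygon(two, polys)
  expect_equal(d2$density, 2 / a1 * 100)

  outside <- tibble::tibble(site_id = "out", lon = -70, lat = 40)
  d3 <- density_by_polygon(dplyr::bind_rows(two, outside), polys)
  expect_equal(d3$count, 2L)
  expect_equal(attr(d3, "unassigned"), "out")
})

test_that("boundary sites are assigned to exactly one polygon by id order", {
  left <- rect(-78.2, 35.0, -78.1, 35.2)
  right <- rect(-78.1, 35.0, -78.0, 35.2)   # shares the -78.1 edge
  polys <- tibble::tibble(polygon_id = c("b", "a"),
                          geometry = list(left, right))
  site <- tibble::tibble(site_id = "edge", lon = -78.1, lat = 35.1)
  d <- density_by_polygon(site, polys)
  expect_equal(sum(d$count), 1L)
  expect_equal(d$count[d$polygon_id == "a"], 1L)  # "a" sorts first
})

test_that("zero-area polygons are rejected", {
  degenerate <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  polys <- tibble::tibble(polygon_id = "z", geometry = list(degenerate))
  site <- tibble::tibble(site_id = "s", lon = 0, lat = 0)
  expect_error(density_by_polygon(site, polys), "zero-area")
})
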