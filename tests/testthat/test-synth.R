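test_that("noise-free scenario yields an exact two-level step", {
  sc <- series_scenario(site_id = "a", noise_sd = 0, dropout_prob = 0,
                        outlier_prob = 0, pre_mean = 3500, post_mean = 800,
                        change_date = "1998-06-15")
  s <- simulate_series(sc)
  pre <- s$value[s$date < as.Date("1998-06-15")]
  post <- s$value[s$date >= as.Date("1998-06-15")]
  expect_true(all(pre == 3500))
  expect_true(all(post == 800))
  expect_setequal(unique(s$value), c(3500, 800))
  # first on/after change date takes the post mean
  first_post <- min(s$date[s$value == 800])
  expect_gte(as.integer(first_post - as.Date("1998-06-15")), 0)
})

test_that("simulation is seed-deterministic", {
  sc <- series_scenario(seed = 42L)
  expect_identical(simulate_series(sc), simulate_series(sc))
  sc2 <- sc; sc2$seed <- 43L
  expect_false(identical(simulate_series(sc), simulate_series(sc2)))
})

test_that("pre-change sample mean honours the CLT bound", {
  sc <- series_scenario(noise_sd = 300, dropout_prob = 0, outlier_prob = 0,
                        change_date = "2000-01-01", seed = 7L)
  s <- simulate_series(sc)
  pre <- s$value[s$date < as.Date("2000-01-01")]
  expect_lt(abs(mean(pre) - 3500), 3 * 300 / sqrt(length(pre)))
})

test_that("1984 artifact produces a third level on pre-change 1984 dates", {
  sc <- series_scenario(noise_sd = 0, dropout_prob = 0, outlier_prob = 0,
                        artifact_1984 = TRUE, artifact_mean = 1200,
                        change_date = "1995-01-01")
  s <- simulate_series(sc)
  expect_setequal(unique(s$value), c(1200, 3500, 800))
  expect_true(all(s$value[format(s$date, "%Y") == "1984"] == 1200))
})

test_that("dropout fraction converges to dropout_prob", {
  sc <- series_scenario(record_start = "1984-01-01", record_end = "2012-12-31",
                        cadence_days = 4L, dropout_prob = 0.2, seed = 11L)
  n_total <- length(seq(sc$record_start, sc$record_end, by = 4))
  s <- simulate_series(sc)
  frac <- 1 - nrow(s) / n_total
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n_total))
})

test_that("total dropout is a degenerate scenario", {
  sc <- series_scenario(dropout_prob = 1)
  expect_error(simulate_series(sc), "degenerate")
})

test_that("scenario invariants are enforced", {
  expect_error(series_scenario(record_start = "2000-01-01",
                               record_end = "1990-01-01"), "precede")
  expect_error(series_scenario(change_date = "2020-01-01"), "window")
  expect_error(series_scenario(noise_sd = -1), ">= 0")
  expect_error(series_scenario(outlier_low = 500), "10,000")
  expect_error(series_scenario(dropout_prob = 1.5), "\\[0, 1\\]")
})

test_that("validation set covers the requested years with aligned truth", {
  tmpl <- series_scenario(noise_sd = 0, dropout_prob = 0, outlier_prob = 0)
  vs <- simulate_validation_set(10, tmpl, c(1990, 1990), seed = 3L)
  expect_true(all(vs$truth$true_change_year == 1990))
  expect_setequal(unique(vs$series$site_id), vs$truth$site_id)

  vs340 <- simulate_validation_set(340, tmpl, c(1987, 2009), seed = 3L)
  expect_equal(nrow(vs340$truth), 340)
  expect_equal(length(unique(vs340$series$site_id)), 340)

  again <- simulate_validation_set(340, tmpl, c(1987, 2009), seed = 3L)
  expect_identical(vs340$truth, again$truth)
  expect_identical(vs340$series, again$series)
})

test_that("landscape generator stays in bbox with known classes", {
  bbox <- c(-78.5, 34.5, -77.5, 35.5)
  ls <- simulate_landscape(25, 12, bbox, seed = 5L)
  expect_true(all(ls$sites$lon >= bbox[1] & ls$sites$lon <= bbox[3]))
  expect_true(all(ls$sites$lat >= bbox[2] & ls$sites$lat <= bbox[4]))
  expect_true(all(ls$features$fclass %in% water_feature_classes()))
  expect_true(all(ls$features$area_km2[ls$features$gtype == "polygon"] > 0))
  expect_true(all(ls$features$area_km2[ls$features$gtype == "linestring"] == 0))
  expect_identical(ls, simulate_landscape(25, 12, bbox, seed = 5L))
})

test_that("a site at a feature centroid is at distance zero downstream", {
  ring <- rbind(c(-78.1, 35.1), c(-78.0, 35.1), c(-78.0, 35.2),
                c(-78.1, 35.2), c(-78.1, 35.1))
  features <- tibble::tibble(feature_id = "f1", fclass = "lake/pond",
                             gtype = "polygon",
                             area_km2 = abs(geosphere::areaPolygon(ring)) / 1e6,
                             geometry = list(ring))
  sites <- tibble::tibble(site_id = "s1", lon = -78.05, lat = 35.15)
  d <- nearest_water_distance(sites, features)
  expect_equal(d$distance_m, 0)
})
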