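fit_stub <- function(date, s1, s2, site_id = "x") {
  s <- make_series(c(rep(s1, 3), rep(s2, 3)),
                   start = as.Date(date) - 3 * 16)
  f <- detect_single_changepoint(s, "mean")
  stopifnot(format(f$changepoint_date, "%Y") == format(as.Date(date), "%Y"))
  f$site_id <- site_id
  f
}

test_that("the three decision rules partition all fits", {
  # (i) changepoint in or before era_start -> PRE_ERA
  e1 <- estimate_construction_year(fit_stub("1985-06-01", 3500, 800))
  expect_equal(e1$kind, "PRE_ERA")
  # (ii) mean rises after era_start -> PRE_ERA
  e2 <- estimate_construction_year(fit_stub("1990-06-01", 800, 3500))
  expect_equal(e2$kind, "PRE_ERA")
  # (iii) mean drops after era_start -> calendar year of first S2 image
  e3 <- estimate_construction_year(fit_stub("1994-06-01", 3500, 800))
  expect_equal(e3$kind, "YEAR")
  expect_equal(e3$year, 1994L)
  expect_true(is.na(e3$flag))
  # beyond era_end: kept but flagged
  e4 <- estimate_construction_year(fit_stub("2011-06-01", 3500, 800))
  expect_equal(e4$kind, "YEAR")
  expect_equal(e4$flag, "post_era")
})

test_that("validation scoring applies the year tolerance and pre-era rules", {
  est <- tibble::tibble(site_id = c("a", "b", "c", "d"),
                        kind = c("YEAR", "PRE_ERA", "YEAR", "YEAR"),
                        year = c(1995L, NA, 2000L, 1990L),
                        flag = NA_character_)
  obs <- tibble::tibble(site_id = c("a", "b", "c", "d"),
                        true_change_year = c(1994L, 1984L, 1990L, 1990L))
  rep <- score_validation(est, obs, tolerance_years = 1)
  expect_equal(rep$n_sites, 4)
  expect_equal(rep$n_correct, 3)      # c is off by 10 years
  expect_equal(rep$accuracy, 0.75)
  expect_equal(rep$mismatches$site_id, "c")
  expect_equal(rep$mismatches$abs_diff_years, 10)

  perfect <- score_validation(
    est[c(1, 4), ], obs[c(1, 4), ] %>%
      dplyr::mutate(true_change_year = c(1995L, 1990L)))
  expect_equal(perfect$accuracy, 1)
  expect_error(score_validation(est, obs[1:3, ]), "one-to-one")
})

test_that("accuracy is non-decreasing in the tolerance", {
  set.seed(21)
  tmpl <- series_scenario(noise_sd = 400, dropout_prob = 0.3,
                          outlier_prob = 0.02)
  vs <- simulate_validation_set(60, tmpl, c(1987, 2009), seed = 21L)
  est <- run_pipeline(vs$series)
  accs <- vapply(0:4, function(tol) {
    score_validation(est, vs$truth, tolerance_years = tol)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("pipeline recovers a noise-free 1993 construction exactly", {
  sc <- series_scenario(noise_sd = 0, dropout_prob = 0, outlier_prob = 0,
                        change_date = "1993-05-10")
  est <- run_pipeline(simulate_series(sc))
  expect_equal(est$kind, "YEAR")
  expect_equal(est$year, 1993L)
})

test_that("pre-era change with a 1984 artifact is classed PRE_ERA", {
  sc <- series_scenario(noise_sd = 200, dropout_prob = 0.1, outlier_prob = 0,
                        change_date = "1985-03-01", artifact_1984 = TRUE,
                        artifact_mean = 1500, seed = 17L)
  est <- run_pipeline(simulate_series(sc))
  expect_equal(est$kind, "PRE_ERA")
})

test_that("inverted (rising-mean) changes are always PRE_ERA", {
  for (seed in 1:10) {
    sc <- series_scenario(pre_mean = 800, post_mean = 3500, noise_sd = 300,
                          dropout_prob = 0.2, outlier_prob = 0.01,
                          change_date = "1995-06-01", seed = seed)
    est <- run_pipeline(simulate_series(sc))
    expect_equal(est$kind, "PRE_ERA")
  }
})

test_that("empty input yields an empty estimate table, not an error", {
  empty <- tibble::tibble(site_id = character(), date = as.Date(character()),
                          value = numeric())
  est <- run_pipeline(empty)
  expect_equal(nrow(est), 0)
  expect_equal(nrow(attr(est, "skipped")), 0)
})

test_that("per-site failures are skipped, not fatal", {
  good <- make_series(c(rep(3500, 4), rep(800, 4)), site_id = "good")
  bad <- make_series(c(12000, 15000), site_id = "bad")  # cleaning empties it
  est <- run_pipeline(dplyr::bind_rows(bad, good))
  expect_equal(est$site_id, "good")
  skipped <- attr(est, "skipped")
  expect_equal(skipped$site_id, "bad")
  expect_match(skipped$reason, "unusable")
})
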