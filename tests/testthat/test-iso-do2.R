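test_that("band extraction matches a brute-force scan and weights encode proximity", {
  set.seed(71)
  grid <- tibble::tibble(
    hb = runif(2000, 7, 13), ci = runif(2000, 1.2, 3.0)
  )
  grid$do2i <- do2i(grid$ci, grid$hb)
  band <- extract_iso_band(grid, level = 330, tolerance = 5)
  brute <- grid[abs(grid$do2i - 330) <= 5, ]
  expect_equal(nrow(band), nrow(brute))
  expect_setequal(band$do2i, brute$do2i)
  expect_true(all(band$weight > 0 & band$weight <= 1))
  expect_equal(band$weight, pmax(1 - abs(band$do2i - 330) / 5, 1e-8))
  # weight is maximal on the level itself
  exact <- noise_free_band(330)
  wb <- extract_iso_band(exact, 330, tolerance = 5)
  expect_true(all(wb$weight > 1 - 1e-9))
})

test_that("zero tolerance keeps only exact-level rows and empty bands fail", {
  data <- tibble::tibble(hb = c(10, 11), ci = c(2, 2.2),
                         do2i = c(300, 310))
  band <- extract_iso_band(data, 300, tolerance = 0)
  expect_equal(nrow(band), 1)
  expect_equal(band$weight, 1)
  expect_error(extract_iso_band(data, 500, tolerance = 5), "insufficient data")
})

test_that("the weighted quadratic tracks the closed-form curve on noise-free bands", {
  for (level in c(280, 330, 380)) {
    band <- extract_iso_band(noise_free_band(level), level, tolerance = 10)
    fit <- fit_iso_quadratic(band)
    hb_grid <- seq(fit$hb_range[1], fit$hb_range[2], length.out = 400)
    oracle <- closed_form_curve(level)(hb_grid)
    expect_lt(max(abs(predict(fit, hb_grid) - oracle)), 0.05)
  }
})

test_that("collinear bands fit with a vanishing quadratic term", {
  hb <- seq(8, 12, length.out = 50)
  band <- tibble::tibble(hb = hb, ci = 3 - 0.1 * hb,
                         do2i = 300, weight = 1)
  attr(band, "level") <- 300; attr(band, "tolerance") <- 10
  # an exactly linear band fits perfectly; lm warns about the zero residuals
  fit <- suppressWarnings(fit_iso_quadratic(band))
  expect_equal(unname(fit$coefficients[["a2"]]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[["a1"]]), -0.1, tolerance = 1e-8)
})

test_that("duplicating rows at halved weight leaves the fit unchanged", {
  band <- extract_iso_band(noise_free_band(330, hb = seq(8, 12, 0.1)), 330, 10)
  fit1 <- fit_iso_quadratic(band)
  doubled <- dplyr::bind_rows(band, band)
  doubled$weight <- doubled$weight / 2
  attr(doubled, "level") <- 330; attr(doubled, "tolerance") <- 10
  fit2 <- fit_iso_quadratic(doubled)
  expect_equal(fit1$coefficients, fit2$coefficients)
})

test_that("degenerate bands are rejected", {
  few <- tibble::tibble(hb = rep(c(9, 10, 11), 4), ci = 2,
                        do2i = 300, weight = 1)
  expect_error(fit_iso_quadratic(few), "distinct haemoglobin")
})

test_that("the closed-form curve is a decreasing convex hyperbola that scales with level", {
  f280 <- closed_form_curve(280)
  expect_equal(f280(8), 280 / (10 * 1.36 * 8))
  hb <- seq(6, 14, 0.25)
  ci <- f280(hb)
  expect_true(all(diff(ci) < 0))                  # strictly decreasing
  expect_true(all(diff(diff(ci)) > 0))            # convex
  expect_equal(closed_form_curve(560)(hb), 2 * ci)  # proportional in level
  expect_equal(f280(24), f280(12) / 2)            # inverse in Hb: ci -> 0 as hb grows
})

test_that("fit evaluation never extrapolates beyond the band's Hb support", {
  band <- extract_iso_band(noise_free_band(330, hb = seq(9, 11, 0.05)), 330, 10)
  fit <- fit_iso_quadratic(band)
  expect_true(is.na(predict(fit, 8)))
  expect_true(is.na(predict(fit, 12)))
  expect_false(is.na(predict(fit, 10)))
  expect_false(is.na(predict(fit, 8, clip_to_domain = FALSE)))
})

test_that("tidy and glance summarise fits in broom style", {
  cohort <- small_cohort(n = 8, seed = 73)
  platform <- truth_platform(cohort) |>
    apply_gdp_constraints() |>
    density_filter(gdp_thresholds(min_bin_count = 20))
  fits <- fit_iso_curves(platform, levels = c(280, 330), tolerance = 15)
  td <- tidy(fits)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_named(td, c("level", "term", "estimate", "std.error"))
  gl <- glance(fits)
  expect_equal(gl$level, c(280, 330))
  expect_true(all(gl$n_points >= 10))
  expect_true(all(gl$hb_min < gl$hb_max))
})

test_that("flow recommendations reproduce the goal-directed worked values", {
  rec <- recommend_flow(hb = 8, bsa = 1.95, level = 280)
  expect_equal(rec$ci_rounded, 2.6)
  expect_equal(rec$ci, 280 / (10 * 1.36 * 8))
  expect_equal(rec$flow, rec$ci * 1.95)
  # at Hb 10 the conventional 2.2 L/min/m^2 set point already meets the goal
  rec10 <- recommend_flow(hb = 10, bsa = 1.95, level = 280)
  expect_equal(round(rec10$ci, 2), 2.06)
  expect_lte(rec10$ci, 2.2)
  # zero target needs zero flow
  expect_equal(recommend_flow(hb = 10, level = 0)$ci, 0)
  # recommendations are exact inverses of delivery
  expect_equal(do2i(rec$ci, hb = 8), 280)
})
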