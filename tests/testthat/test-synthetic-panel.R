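test_that("panel generator configuration is validated field by field", {
  expect_error(panel_gen_config(n_units = 1), "n_units")
  expect_error(panel_gen_config(n_periods = 1), "n_periods")
  expect_error(panel_gen_config(threshold_star = 0.9), "threshold_star")
  expect_error(panel_gen_config(slope_ratio = 0.5), "slope_ratio")
  expect_error(panel_gen_config(mh_improve_frac = 1), "mh_improve_frac")
  expect_error(panel_gen_config(noise_sd_mh = -1), "noise_sd_mh")
  expect_error(panel_gen_config(rho = 1.2), "rho")
})

test_that("same config and seed reproduce the bundle exactly", {
  a <- gen_panel(panel_gen_config(n_units = 8, seed = 11))
  b <- gen_panel(panel_gen_config(n_units = 8, seed = 11))
  expect_identical(a, b)
  c <- gen_panel(panel_gen_config(n_units = 8, seed = 12))
  expect_false(identical(a$panel, c$panel))
  # truth echoes the config
  expect_equal(a$truth$threshold_star, 0.38)
  expect_equal(a$truth$slope_ratio, 3.3)
  expect_equal(a$provenance$seed, 11)
})

test_that("noiseless disease outcome is exactly piecewise linear with kink at the threshold", {
  b <- gen_panel(panel_gen_config(n_units = 10, noise_sd_disease = 0, seed = 3))
  p <- b$panel
  tr <- b$truth
  controls <- as.matrix(p[, names(tr$control_beta)])
  systematic <- tr$slope_below * p$coverage +
    (tr$slope_ratio - 1) * tr$slope_below * pmax(p$coverage - tr$threshold_star, 0) +
    as.numeric(controls %*% tr$control_beta)
  resid <- p$chronic_rate - systematic
  # what remains is the unit fixed effect: constant within unit
  expect_lt(max(abs(resid - ave(resid, p$unit))), 1e-12)
})

test_that("generated coverage stays in support and spans the threshold", {
  b <- gen_panel(panel_gen_config(n_units = 30, seed = 5))
  g <- b$panel$coverage
  expect_true(all(g >= 0.05 & g <= 0.85))
  expect_true(min(g) < 0.38 && max(g) > 0.38)
  expect_false(anyDuplicated(b$panel[c("unit", "year")]) > 0)
  expect_equal(nrow(b$panel), 30 * 14)
})

test_that("truth records the closed-form location-scale quantile slopes", {
  b <- gen_panel(panel_gen_config(seed = 7))
  qs <- b$truth$quantile_slopes
  expect_equal(qs[["tau_0.25"]], -0.89 + 0.519 * qnorm(0.25))
  expect_equal(round(qs[["tau_0.25"]], 2), -1.24)
  expect_equal(qs[["tau_0.5"]], -0.89)
  expect_equal(round(qs[["tau_0.75"]], 2), -0.54)
})

test_that("empirical moments converge to the planted truth on large panels", {
  b <- gen_panel(panel_gen_config(n_units = 300, seed = 21))
  p <- b$panel
  tr <- b$truth
  # mental-score location: regression on coverage + regime dummy recovers
  # the planted median slope (the mean and median of the location-scale
  # model coincide)
  above <- as.numeric(p$coverage > tr$threshold_star)
  fit <- lm(mental_score ~ coverage + above, data = cbind(p, above = above))
  se <- summary(fit)$coefficients["coverage", "Std. Error"]
  expect_lt(abs(coef(fit)[["coverage"]] - tr$mh_beta_median), 3 * se)
  # disease slope below threshold
  below <- p[p$coverage <= tr$threshold_star, ]
  fitd <- fit_fe(below, "chronic_rate", c("coverage", names(tr$control_beta)))
  expect_lt(abs(fitd$beta_g - tr$slope_below), 3 * fitd$se[[1]])
})

test_that("panel CSV round-trips", {
  b <- gen_panel(panel_gen_config(n_units = 4, n_periods = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(b$panel, path)
  back <- read_panel_csv(path)
  expect_equal(back$coverage, b$panel$coverage)
  expect_equal(back$unit, b$panel$unit)
})
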