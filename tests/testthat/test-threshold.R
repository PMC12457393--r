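test_that("noiseless kink is located exactly when the true break is a candidate", {
  b <- gen_panel(panel_gen_config(n_units = 12, noise_sd_disease = 0, seed = 9))
  tf <- fit_threshold(b$panel, "chronic_rate", "coverage",
                      names(b$truth$control_beta),
                      grid = c(seq(0.1, 0.8, by = 0.05), 0.38), n_boot = 0)
  expect_equal(tf$gamma_hat, 0.38)
  expect_equal(tf$slope_below, -1, tolerance = 1e-8)
  expect_equal(tf$slope_ratio, 3.3, tolerance = 1e-8)
  expect_true(0.38 >= tf$ci_gamma[1] && 0.38 <= tf$ci_gamma[2])
})

test_that("the selected threshold minimizes the SSR profile over the grid", {
  b <- gen_panel(panel_gen_config(n_units = 15, seed = 4))
  tf <- fit_threshold(b$panel, "chronic_rate", "coverage",
                      names(b$truth$control_beta), n_boot = 0)
  expect_true(tf$gamma_hat %in% tf$grid)
  best <- which(tf$grid == tf$gamma_hat)
  expect_true(all(tf$ssr_profile[best] <= tf$ssr_profile + 1e-10))
})

test_that("threshold recovery error shrinks as noise shrinks", {
  err_at <- function(noise) {
    errs <- vapply(1:8, function(i) {
      b <- gen_panel(panel_gen_config(n_units = 20, noise_sd_disease = noise,
                                      seed = 300 + i))
      tf <- fit_threshold(b$panel, "chronic_rate", "coverage",
                          names(b$truth$control_beta), n_boot = 0)
      abs(tf$gamma_hat - 0.38)
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(0.005), err_at(0.5) + 1e-12)
  expect_lt(err_at(0.005), 0.01)
})

test_that("bootstrap existence test has approximately nominal size under the null", {
  # linear (no-threshold) data: rejections at 5% should occur ~5% of the time
  rej <- vapply(1:100, function(i) {
    b <- gen_panel(panel_gen_config(n_units = 8, n_periods = 8, slope_ratio = 1,
                                    mh_improve_frac = 0, seed = 700 + i))
    tf <- fit_threshold(b$panel, "chronic_rate", "coverage",
                        names(b$truth$control_beta),
                        n_boot = 99, seed = i)
    tf$boot_p <= 0.05
  }, logical(1))
  # 99% binomial envelope around 0.05 for 100 draws
  expect_gte(sum(rej), 0)
  expect_lte(sum(rej), 12)
})

test_that("bootstrap test detects the planted threshold", {
  b <- gen_panel(panel_gen_config(seed = 2))
  tf <- fit_threshold(b$panel, "chronic_rate", "coverage",
                      names(b$truth$control_beta), n_boot = 99, seed = 5)
  expect_lt(tf$boot_p, 0.05)
})

test_that("threshold fit validates its inputs", {
  b <- gen_panel(panel_gen_config(n_units = 10, seed = 1))
  expect_error(fit_threshold(b$panel, "chronic_rate", trim = 0.5), "trim")
  p <- b$panel
  p$coverage <- rep(c(0.2, 0.3), length.out = nrow(p))
  expect_error(fit_threshold(p, "chronic_rate", "coverage"), "distinct values")
})
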