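# Least-squares fitting of the forward and inverse models.

test_that("noise-free forward fit recovers the generating constants", {
  truth <- forward_params(a = -50.75, b = -47.6, p = 3.8, h = 0.037,
                          q = 0.04, i = 0.037, "unit_offset")
  tab <- clean_table(standard_design(), truth)
  est <- fit_forward(tab, mode = "unit_offset")
  for (nm in c("a", "b", "p", "h", "q", "i")) {
    expect_lt(rel_err(est[[nm]], truth[[nm]]), 1e-6)
  }
  expect_true(attr(est, "fit")$converged)
})

test_that("single-analyte table reduces to a two-parameter log fit", {
  truth <- forward_params(a = -50.75, b = -47.6, p = 3.8, h = 0,
                          q = 0.04, i = 0.5, "bare")
  des <- make_design(c(0.1, 0.25, 0.5, 1), 0)
  tab <- clean_table(des, truth)
  # i multiplies y = 0 everywhere, so it is fixed at an arbitrary value
  est <- fit_forward(tab, mode = "bare", fix = c(h = 0, i = 0.5))
  expect_lt(rel_err(est$a, truth$a), 1e-6)
  expect_lt(rel_err(est$p, truth$p), 1e-6)
  expect_identical(est$h, 0)
})

test_that("forward fit flags unidentifiable sensitivities", {
  truth <- bare_params()
  tab <- clean_table(make_design(c(0.1, 0.25, 0.5, 1), 0), truth)
  expect_error(fit_forward(tab, mode = "bare"), "unidentifiable")
})

test_that("forward slopes survive 1 mV noise on the replicated design", {
  truth <- default_forward_params()
  des <- standard_design()
  errs <- vapply(1:20, function(s) {
    cfg <- simulation_config(des, truth, noise_sd = 1, n_replicates = 4,
                             seed = 1000 + s)
    est <- fit_forward(as_calibration_table(simulate_panel(cfg)))
    c(rel_err(est$a, truth$a), rel_err(est$b, truth$b))
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 0.05)
  expect_lt(stats::median(errs[2, ]), 0.05)
})

test_that("two-stage fit is exact on bare-model data with no interaction", {
  tab <- clean_table(bare_design(), bare_params())
  fit <- fit_inversion(tab, strategy = "two_stage", mode = "bare")
  expect_equal(fit$r2_x, 1, tolerance = 1e-9)
  expect_equal(fit$r2_y, 1, tolerance = 1e-9)
  expect_lt(abs(fit$params$c), 1e-6)
  expect_lt(abs(fit$params$d), 1e-6)
  expect_true(fit$converged)
})

test_that("direct fit of the factorial design reaches calibration-grade R^2", {
  cfg <- simulation_config(standard_design(), noise_sd = 0, seed = 1)
  tab <- as_calibration_table(simulate_panel(cfg))
  fit <- fit_inversion(tab, strategy = "direct")
  expect_gte(fit$r2_x, 0.996)
  expect_length(fit$residuals_x, nrow(tab))
  expect_length(fit$residuals_y, nrow(tab))
  expect_lte(fit$r2_x, 1)
  expect_lte(fit$r2_y, 1)
})

test_that("underdetermined tables raise an identifiability error", {
  tab <- clean_table(bare_design(), bare_params())[1:5, ]
  expect_error(fit_inversion(tab), "deficit")
})

test_that("fitting is deterministic: same table, identical result", {
  cfg <- simulation_config(standard_design(), noise_sd = 1, seed = 99)
  tab <- as_calibration_table(simulate_panel(cfg))
  f1 <- fit_inversion(tab, strategy = "direct")
  f2 <- fit_inversion(tab, strategy = "direct")
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$residuals_x, f2$residuals_x)
  expect_identical(f1$r2_x, f2$r2_x)
})

test_that("noisy calibrations predict held-out clean responses to < 0.05 mM", {
  truth <- default_forward_params()
  des <- standard_design()
  clean <- clean_table(des, truth)
  rmse <- vapply(1:20, function(s) {
    cfg <- simulation_config(des, truth, noise_sd = 1, seed = 2000 + s)
    fit <- fit_inversion(as_calibration_table(simulate_panel(cfg)),
                         strategy = "direct")
    pred <- predict_concentrations(clean$F_mV, clean$G_mV, fit$params)
    sqrt(mean((pred$x_hat_mM - clean$x_mM)^2))
  }, numeric(1))
  expect_lt(stats::median(rmse), 0.05)
})
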