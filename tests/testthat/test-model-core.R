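# Forward model, analytic inversion, interaction terms, prediction.

test_that("relative and CPA values are the defined potential differences", {
  out <- compute_outputs(Vr = 10, Vs = -40, Vr_after = -5)
  expect_equal(out$relative_mV, -50)
  expect_equal(out$cpa_mV, -15)

  expect_equal(unlist(compute_outputs(0, 0, 0)), c(relative_mV = 0, cpa_mV = 0))

  # magnitudes on the ~-80 mV scale of a 1 mM acesulfame K reading
  out <- compute_outputs(Vr = -3.2, Vs = -83.2, Vr_after = -20.0)
  expect_equal(out$relative_mV, -80.0)
  expect_equal(out$cpa_mV, -16.8)

  expect_error(compute_outputs(NA, 0, 0), "Vr")
  expect_error(compute_outputs(0, Inf, 0), "Vs")
  expect_error(compute_outputs(0, 0, NaN), "Vr_after")
})

test_that("forward response evaluates the logarithmic model in both modes", {
  fp <- default_forward_params()
  blank <- forward_response(0, 0, fp)
  expect_identical(blank$F_mV, 0)  # log(1) = 0, exact in unit_offset mode
  expect_identical(blank$G_mV, 0)

  # bare mode: ln(e) = 1, so F = a exactly
  bp <- forward_params(a = -50, b = -50, p = 1, h = 0, q = 0, i = 1,
                       offset_mode = "bare")
  expect_equal(forward_response(exp(1), 1, bp)$F_mV, -50)

  expect_error(forward_response(0, 0, bp), "blank cannot be modelled")

  # anchors invert the scalar log expression: re-evaluating must hit them
  expect_equal(forward_response(1, 0, fp)$F_mV, -80, tolerance = 1e-9)
  expect_equal(forward_response(0, 50, fp)$G_mV, -50, tolerance = 1e-9)
  expect_equal(fp$p, exp(80 / 50.75) - 1, tolerance = 1e-12)
  expect_equal(fp$i, (exp(50 / 47.6) - 1) / 50, tolerance = 1e-12)
})

test_that("forward params validate slopes, signs and singularity", {
  expect_error(forward_params(0, -50, 1, 0, 0, 1), "nonzero")
  expect_error(forward_params(-50, -50, -1, 0, 0, 1), "nonnegative")
  expect_error(forward_params(-50, -50, 1, 1, 1, 1), "singular")
  expect_error(forward_response(-0.1, 0, default_forward_params()),
               "nonnegative")
})

test_that("inversion constants are the exact 2x2 inverse", {
  idp <- forward_params(-50, -50, p = 1, h = 0, q = 0, i = 1, "bare")
  expect_equal(derive_inversion_constants(idp),
               c(j = 1, k = 0, m = 0, n = 1))

  dg <- forward_params(-50, -50, p = 2, h = 0, q = 0, i = 4, "bare")
  expect_equal(derive_inversion_constants(dg),
               c(j = 0.5, k = 0, m = 0, n = 0.25))
})

test_that("inversion constants match an independent matrix-inverse oracle", {
  set.seed(11)
  for (rep in 1:100) {
    s <- stats::runif(4, 0.01, 10)
    M <- matrix(s, 2, 2, byrow = TRUE)  # [[p, h], [q, i]]
    if (abs(det(M)) < 1e-3) next
    fp <- forward_params(-50, -50, p = s[1], h = s[2], q = s[3], i = s[4],
                         offset_mode = "bare")
    ours <- derive_inversion_constants(fp)
    oracle <- solve(M)  # independent of the closed-form expressions
    expect_equal(ours[["j"]], oracle[1, 1], tolerance = 1e-12)
    expect_equal(ours[["k"]], oracle[1, 2], tolerance = 1e-12)
    expect_equal(ours[["m"]], oracle[2, 1], tolerance = 1e-12)
    expect_equal(ours[["n"]], oracle[2, 2], tolerance = 1e-12)
  }
})

test_that("interaction correction vanishes iff the sensors agree", {
  expect_identical(interaction_correction(-37.2, -37.2, 5, -20), 0)
  expect_identical(interaction_correction(0, 0, 114.51, -54.35), 0)

  # hand evaluation with the published (c, e) pair at F - G = e
  expect_equal(interaction_correction(-16.92, 0, -0.024, -16.92),
               -0.024 * (exp(1) - 1), tolerance = 1e-12)

  expect_error(interaction_correction(1, 0, 1, 0), "nonzero")
})

test_that("prediction at the blank matches the published-constant arithmetic", {
  pp <- reference_inversion_params()
  pred <- predict_concentrations(0, 0, pp)
  expect_equal(pred$x_hat_mM, 0.50 - 0.49, tolerance = 1e-12)   #  0.01 mM
  expect_equal(pred$y_hat_mM, -177.45 + 176.35, tolerance = 1e-12)  # -1.10 mM
})

test_that("prediction inverts the forward model exactly when derived from it", {
  fp <- bare_params()
  lin <- derive_inversion_constants(fp)
  pp <- inversion_params(a = fp$a, b = fp$b,
                         j = lin[["j"]], k = lin[["k"]],
                         m = lin[["m"]], n = lin[["n"]],
                         c = 0, d = 0, e = -20, f = -50)
  set.seed(7)
  x <- stats::runif(50, 0.01, 1); y <- stats::runif(50, 0.5, 50)
  resp <- forward_response(x, y, fp)
  pred <- predict_concentrations(resp$F_mV, resp$G_mV, pp)
  expect_lt(max(rel_err(pred$x_hat_mM, x)), 1e-9)
  expect_lt(max(rel_err(pred$y_hat_mM, y)), 1e-9)

  # exp cancels log for identity sensitivities: F = a ln 2 maps back to 2 mM
  idp <- inversion_params(a = -50, b = -47, j = 1, k = 0, m = 0, n = 1,
                          c = 0, d = 0, e = -20, f = -50)
  pred2 <- predict_concentrations(-50 * log(2), -47 * log(2), idp)
  expect_equal(pred2$x_hat_mM, 2, tolerance = 1e-12)
  expect_equal(pred2$y_hat_mM, 2, tolerance = 1e-12)
})

test_that("prediction is invariant to interaction constants when F = G", {
  base <- inversion_params(a = -50.75, b = -47.6, j = 0.5, k = -0.49,
                           m = -177, n = 176, c = 0, d = 0,
                           e = -16.92, f = -54.35)
  set.seed(3)
  for (fg in stats::runif(10, -90, 0)) {
    ref <- predict_concentrations(fg, fg, base)
    alt <- predict_concentrations(fg, fg, inversion_params(
      a = base$a, b = base$b, j = base$j, k = base$k, m = base$m,
      n = base$n, c = stats::runif(1, -5, 5), d = stats::runif(1, -5, 5),
      e = stats::runif(1, 0.5, 60) * sample(c(-1, 1), 1),
      f = stats::runif(1, 0.5, 60) * sample(c(-1, 1), 1)))
    expect_identical(alt$x_hat_mM, ref$x_hat_mM)
    expect_identical(alt$y_hat_mM, ref$y_hat_mM)
  }
})

test_that("responses grow in magnitude with concentration", {
  fp <- default_forward_params()
  for (y in c(0, 10, 30, 50)) {
    Fv <- forward_response(seq(0, 1, by = 0.1), y, fp)$F_mV
    expect_true(all(diff(abs(Fv)) > 0))
  }
  for (x in c(0, 0.25, 0.5, 1)) {
    Gv <- forward_response(x, seq(0, 50, by = 5), fp)$G_mV
    expect_true(all(diff(abs(Gv)) > 0))
  }
})

test_that("blank prediction with published constants stays within 0.05 mM", {
  pred <- predict_concentrations(0, 0, reference_inversion_params())
  expect_lte(abs(pred$x_hat_mM), 0.05)
})

test_that("extreme exponent arguments are clipped with a warning", {
  pp <- inversion_params(a = -1, b = -47.6, j = 0.5, k = -0.49,
                         m = -177, n = 176, c = 0, d = 0,
                         e = -16.92, f = -54.35)
  expect_warning(predict_concentrations(-100, -100, pp), "clipped")
})
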