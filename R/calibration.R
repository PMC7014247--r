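# Fitting the model constants to a calibration table of known mixtures:
# per-sensor forward fits, the two-stage inversion (analytic linear
# constants + interaction corrections on residuals), and the direct joint
# fit of all ten prediction-model constants.

.LM_CONTROL <- minpack.lm::nls.lm.control(maxiter = 1000,
                                          ftol = 1e-10, ptol = 1e-10)
# interaction decay constants are kept away from 0 to avoid overflow
.DECAY_MIN <- 0.1

.check_calibration_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("x_mM", "y_mM", "F_mV", "G_mV")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop(sprintf("calibration table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in need) {
    if (!is.numeric(table[[col]]) || any(!is.finite(table[[col]]))) {
      stop(sprintf("column '%s' must be finite numeric", col), call. = FALSE)
    }
  }
  invisible(table)
}

.n_distinct_points <- function(table) {
  nrow(unique(table[, c("x_mM", "y_mM")]))
}

#' Fit the forward response model to a calibration table
#'
#' Estimates the slope and the two sensitivities of each sensor by
#' nonlinear least squares on the relative values: `(a, p, h)` on the
#' sweetness responses `F` and `(b, q, i)` on the saltiness responses `G`,
#' minimizing squared mV residuals with a trust-region
#' (Levenberg-Marquardt) solver. Sensitivities are constrained
#' nonnegative. The fit is deterministic given the table and the
#' initialization: slopes start at -50 mV (the instrument's response
#' scale) and sensitivities at a linearized regression estimate obtained
#' by regressing `exp(F/a0) - offset` on the concentrations.
#'
#' @param table Calibration table with columns `x_mM`, `y_mM`, `F_mV`,
#'   `G_mV`, one row per (possibly replicated) sample; see
#'   [as_calibration_table()].
#' @param mode `"unit_offset"` (default; required when the table contains
#'   the blank sample) or `"bare"`.
#' @param fix Optional named numeric vector fixing sensitivities at known
#'   values instead of estimating them, e.g. `c(h = 0)` for a table with
#'   no NaCl variation. Names among `p`, `h`, `q`, `i`.
#' @return A [forward_params()] object with a `"fit"` attribute carrying
#'   per-sensor convergence flags, iteration counts and mV residuals.
#' @export
fit_forward <- function(table, mode = c("unit_offset", "bare"), fix = NULL) {
  mode <- match.arg(mode)
  .check_calibration_table(table)
  if (mode == "bare" && any(table$x_mM == 0 & table$y_mM == 0)) {
    stop(paste("table contains a blank (0, 0) sample, which the bare model",
               "cannot represent; use mode = 'unit_offset'"), call. = FALSE)
  }
  if (!is.null(fix)) {
    stopifnot(is.numeric(fix), !is.null(names(fix)),
              all(names(fix) %in% c("p", "h", "q", "i")), all(fix >= 0))
  }
  offset <- if (mode == "unit_offset") 1 else 0

  n_x <- length(unique(table$x_mM))
  n_y <- length(unique(table$y_mM))
  fixed_names <- names(fix)
  for (nm in c("p", "h", "q", "i")) {
    varies <- if (nm %in% c("p", "q")) n_x >= 2 else n_y >= 2
    if (!varies && !(nm %in% fixed_names)) {
      stop(sprintf(
        paste("sensitivity '%s' is unidentifiable: its analyte takes a",
              "single level in the table (fix it or add levels)"), nm),
        call. = FALSE)
    }
  }

  # one sensor: fit slope + the free subset of (sens_x, sens_y)
  fit_one <- function(resp, sx_name, sy_name) {
    a0 <- -50
    # linearized initialization: exp(resp/a0) - offset ~ 0 + x + y
    w <- exp(pmin(pmax(resp / a0, -.EXP_CLIP), .EXP_CLIP)) - offset
    free <- setdiff(c(sx_name, sy_name), fixed_names)
    design_cols <- list(table$x_mM, table$y_mM)
    names(design_cols) <- c(sx_name, sy_name)
    w_adj <- w
    for (nm in intersect(c(sx_name, sy_name), fixed_names)) {
      w_adj <- w_adj - fix[[nm]] * design_cols[[nm]]
    }
    init <- c(slope = a0)
    if (length(free)) {
      X <- do.call(cbind, design_cols[free])
      ls0 <- tryCatch(stats::coef(stats::lm.fit(X, w_adj)),
                      error = function(e) rep(NA_real_, length(free)))
      ls0[!is.finite(ls0)] <- 0.01
      init <- c(init, pmax(ls0, 1e-6))
      names(init) <- c("slope", free)
    }
    resid_fn <- function(par) {
      sens <- c(fix, par[free])
      arg <- offset + sens[[sx_name]] * table$x_mM +
        sens[[sy_name]] * table$y_mM
      arg <- pmax(arg, 1e-12)  # keep the log defined along the search path
      resp - par[["slope"]] * log(arg)
    }
    lower <- c(-Inf, rep(0, length(free)))
    fit <- minpack.lm::nls.lm(init, fn = resid_fn, lower = lower,
                              control = .LM_CONTROL)
    sens <- c(fix, stats::coef(fit)[free])
    list(slope = stats::coef(fit)[["slope"]],
         sens_x = sens[[sx_name]], sens_y = sens[[sy_name]],
         converged = fit$info %in% 1:4, n_iterations = fit$niter,
         residuals = -fit$fvec)
  }

  f_fit <- fit_one(table$F_mV, "p", "h")
  g_fit <- fit_one(table$G_mV, "q", "i")
  for (s in list(f_fit, g_fit)) {
    if (!s$converged) {
      warning("forward fit did not converge within the iteration cap",
              call. = FALSE)
    }
  }
  out <- forward_params(a = f_fit$slope, b = g_fit$slope,
                        p = f_fit$sens_x, h = f_fit$sens_y,
                        q = g_fit$sens_x, i = g_fit$sens_y,
                        offset_mode = mode)
  attr(out, "fit") <- list(
    converged = f_fit$converged && g_fit$converged,
    n_iterations = c(F = f_fit$n_iterations, G = g_fit$n_iterations),
    residuals_F = f_fit$residuals, residuals_G = g_fit$residuals)
  out
}

# fit one interaction pair (amplitude, decay) to concentration residuals;
# decay stays on the negative side of the +/- .DECAY_MIN exclusion zone,
# matching the negative-going decays of this sensor family
.fit_interaction <- function(resid, dFG, decay0) {
  if (max(resid) - min(resid) < 1e-6) {
    return(list(scale = 0, decay = decay0, converged = TRUE, n_iterations = 0L))
  }
  fn <- function(par) {
    resid - par[["scale"]] *
      (exp(pmin(pmax(dFG / par[["decay"]], -.EXP_CLIP), .EXP_CLIP)) - 1)
  }
  fit <- minpack.lm::nls.lm(c(scale = 0, decay = decay0), fn = fn,
                            lower = c(-Inf, -Inf),
                            upper = c(Inf, -.DECAY_MIN),
                            control = .LM_CONTROL)
  list(scale = stats::coef(fit)[["scale"]],
       decay = stats::coef(fit)[["decay"]],
       converged = fit$info %in% 1:4, n_iterations = fit$niter)
}

#' Fit the full inverse prediction model
#'
#' Estimates the ten constants of the interaction-corrected inverse model
#' from a calibration table of known mixtures and measured relative
#' values.
#'
#' Two strategies are available:
#' \describe{
#'   \item{`two_stage` (default)}{(1) fit the forward model with
#'     [fit_forward()]; (2) derive the linear constants `(j, k, m, n)`
#'     analytically with [derive_inversion_constants()], carrying the
#'     slopes `(a, b)` over; (3) fit the interaction pair `(c, e)` by
#'     least squares on the acesulfame K residuals and `(d, f)` on the
#'     NaCl residuals. Exact on data generated by a bare forward model.}
#'   \item{`direct`}{jointly refit all ten constants to the
#'     `(F, G) -> (x, y)` map by trust-region least squares, starting from
#'     the two-stage solution. Concentration residuals are standardized
#'     per analyte (NaCl residuals divided by the design's maximum NaCl
#'     level) so that neither analyte dominates the cost. Preferred when
#'     the responses contain structure the bare model cannot represent,
#'     e.g. a finite blank response.}
#' }
#'
#' @param table Calibration table (columns `x_mM`, `y_mM`, `F_mV`,
#'   `G_mV`); needs at least 10 distinct design points and two distinct
#'   levels of each analyte.
#' @param strategy `"two_stage"` or `"direct"`.
#' @param mode Forward-model mode passed to [fit_forward()];
#'   `"unit_offset"` by default.
#' @param seed Optional integer recorded in the result for provenance (the
#'   fit itself is deterministic).
#' @return An object of class `fit_result`: the fitted
#'   [inversion_params()], the intermediate [forward_params()],
#'   per-sample concentration residuals, `r2_x`, `r2_y`, `rmse_x`,
#'   `rmse_y`, a convergence flag and iteration count.
#' @examples
#' cfg <- simulation_config(make_design(c(0, 0.25, 0.5, 1), c(0, 10, 30, 50)),
#'                          noise_sd = 0, seed = 1)
#' fit <- fit_inversion(as_calibration_table(simulate_panel(cfg)),
#'                      strategy = "direct")
#' fit$r2_x
#' @export
fit_inversion <- function(table, strategy = c("two_stage", "direct"),
                          mode = c("unit_offset", "bare"), seed = NULL) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  .check_calibration_table(table)
  n_pts <- .n_distinct_points(table)
  n_const <- 10L
  if (n_pts < n_const) {
    stop(sprintf(
      paste("identifiability: the full model has %d constants but the table",
            "has only %d distinct design point(s) (deficit %d)"),
      n_const, n_pts, n_const - n_pts), call. = FALSE)
  }
  if (length(unique(table$x_mM)) < 2 || length(unique(table$y_mM)) < 2) {
    stop("need at least two distinct levels of each analyte", call. = FALSE)
  }

  # stage 1-2: forward fit and analytic linear inversion
  fwd <- fit_forward(table, mode = mode)
  lin <- derive_inversion_constants(fwd)
  ef <- exp(pmin(pmax(table$F_mV / fwd$a, -.EXP_CLIP), .EXP_CLIP))
  eg <- exp(pmin(pmax(table$G_mV / fwd$b, -.EXP_CLIP), .EXP_CLIP))
  rx <- table$x_mM - (lin[["j"]] * ef + lin[["k"]] * eg)
  ry <- table$y_mM - (lin[["m"]] * ef + lin[["n"]] * eg)

  # stage 3: interaction corrections on the concentration residuals
  dFG <- table$F_mV - table$G_mV
  ce <- .fit_interaction(rx, dFG, decay0 = -20)
  df <- .fit_interaction(ry, dFG, decay0 = -50)
  params <- inversion_params(
    a = fwd$a, b = fwd$b,
    j = lin[["j"]], k = lin[["k"]], m = lin[["m"]], n = lin[["n"]],
    c = ce$scale, d = df$scale,
    e = ce$decay, f = df$decay)
  converged <- attr(fwd, "fit")$converged && ce$converged && df$converged
  n_iter <- sum(attr(fwd, "fit")$n_iterations, ce$n_iterations,
                df$n_iterations)

  if (strategy == "direct") {
    y_scale <- max(abs(table$y_mM))
    if (y_scale == 0) y_scale <- 1
    theta0 <- unlist(params[c("a", "b", "j", "k", "m", "n", "c", "d",
                              "e", "f")])
    resid_fn <- function(th) {
      pr <- predict_concentrations(table$F_mV, table$G_mV,
                                   .theta_to_params(th))
      c(pr$x_hat_mM - table$x_mM, (pr$y_hat_mM - table$y_mM) / y_scale)
    }
    lower <- rep(-Inf, 10)
    upper <- c(rep(Inf, 8), -.DECAY_MIN, -.DECAY_MIN)
    fit <- suppressWarnings(
      minpack.lm::nls.lm(theta0, fn = resid_fn, lower = lower,
                         upper = upper, control = .LM_CONTROL))
    params <- .theta_to_params(stats::coef(fit))
    converged <- fit$info %in% 1:4
    n_iter <- fit$niter
    if (!converged) {
      warning("direct fit did not converge within the iteration cap",
              call. = FALSE)
    }
  }

  pred <- predict_concentrations(table$F_mV, table$G_mV, params)
  res <- structure(
    list(params = params, forward = fwd, strategy = strategy,
         residuals_x = table$x_mM - pred$x_hat_mM,
         residuals_y = table$y_mM - pred$y_hat_mM,
         r2_x = r_squared(table$x_mM, pred$x_hat_mM),
         r2_y = r_squared(table$y_mM, pred$y_hat_mM),
         rmse_x = sqrt(mean((table$x_mM - pred$x_hat_mM)^2)),
         rmse_y = sqrt(mean((table$y_mM - pred$y_hat_mM)^2)),
         converged = converged, n_iterations = as.integer(n_iter),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "fit_result")
  res
}

.theta_to_params <- function(th) {
  inversion_params(a = th[["a"]], b = th[["b"]], j = th[["j"]],
                   k = th[["k"]], m = th[["m"]], n = th[["n"]],
                   c = th[["c"]], d = th[["d"]], e = th[["e"]],
                   f = th[["f"]])
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Inverse model fit (%s strategy)\n", x$strategy))
  cat(sprintf("  %d calibration rows, %sconverged in %d iterations\n",
              length(x$residuals_x), if (x$converged) "" else "NOT ",
              x$n_iterations))
  cat(sprintf("  acesulfame K: R^2 = %.4f, RMSE = %.4g mM\n",
              x$r2_x, x$rmse_x))
  cat(sprintf("  NaCl:         R^2 = %.4f, RMSE = %.4g mM\n",
              x$r2_y, x$rmse_y))
  print(x$params)
  invisible(x)
}
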