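# Core mathematics of the two-sensor cross-interference model:
# logarithmic forward response, analytic linear inversion, exponential
# interaction corrections, and the full response -> concentration map.

# Exponent arguments beyond this magnitude indicate a broken fit, not a
# measurement; they are clipped before exponentiation (with a warning).
.EXP_CLIP <- 50

.clipped_exp <- function(z, what = "exponent") {
  out <- abs(z) > .EXP_CLIP
  if (any(out, na.rm = TRUE)) {
    warning(sprintf("%d %s argument(s) exceeded |%g| and were clipped",
                    sum(out, na.rm = TRUE), what, .EXP_CLIP), call. = FALSE)
    z <- pmin(pmax(z, -.EXP_CLIP), .EXP_CLIP)
  }
  exp(z)
}

.check_finite_scalar <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  as.numeric(value)
}

#' Forward response-model constants
#'
#' Bundles the six constants of the logarithmic forward model that maps a
#' two-analyte mixture to the pair of sensor relative values:
#' \deqn{F = a \ln(p x + h y), \qquad G = b \ln(q x + i y)}
#' where `x` is the acesulfame K concentration (mM), `y` the NaCl
#' concentration (mM), `F` the sweetness-sensor and `G` the saltiness-sensor
#' relative value (mV). In `"unit_offset"` mode the log arguments are
#' `1 + p*x + h*y` and `1 + q*x + i*y`, which pins the blank response
#' `F(0,0) = G(0,0) = 0` and keeps the model defined at zero concentration;
#' the `"bare"` mode is the form above, exactly invertible by
#' [derive_inversion_constants()] but undefined at the blank.
#'
#' @param a,b Sensor slopes in mV (sweetness, saltiness); must be nonzero.
#'   Responses in this system are negative-going, so slopes are typically
#'   around -50 mV.
#' @param p,h Sweetness-sensor sensitivities to acesulfame K and NaCl
#'   (1/mM); nonnegative.
#' @param q,i Saltiness-sensor sensitivities to acesulfame K and NaCl
#'   (1/mM); nonnegative.
#' @param offset_mode `"unit_offset"` (default) or `"bare"`; see Details.
#'
#' @return An object of class `forward_params`.
#' @seealso [forward_response()], [derive_inversion_constants()],
#'   [default_forward_params()]
#' @examples
#' fp <- forward_params(a = -50.75, b = -47.6,
#'                      p = 3.8, h = 0.029, q = 0.23, i = 0.037)
#' forward_response(1, 0, fp)
#' @export
forward_params <- function(a, b, p, h, q, i,
                           offset_mode = c("unit_offset", "bare")) {
  offset_mode <- match.arg(offset_mode)
  a <- .check_finite_scalar(a, "a"); b <- .check_finite_scalar(b, "b")
  p <- .check_finite_scalar(p, "p"); h <- .check_finite_scalar(h, "h")
  q <- .check_finite_scalar(q, "q"); i <- .check_finite_scalar(i, "i")
  if (a == 0 || b == 0) {
    stop("slopes 'a' and 'b' must be nonzero", call. = FALSE)
  }
  if (any(c(p, h, q, i) < 0)) {
    stop("sensitivities p, h, q, i must be nonnegative", call. = FALSE)
  }
  det <- p * i - h * q
  if (det == 0) {
    stop(sprintf(
      "sensitivity matrix [[p, h], [q, i]] is singular (determinant = %g)",
      det), call. = FALSE)
  }
  structure(
    list(a = a, b = b, p = p, h = h, q = q, i = i, offset_mode = offset_mode),
    class = "forward_params")
}

#' @export
print.forward_params <- function(x, ...) {
  cat("Forward response model (", x$offset_mode, " mode)\n", sep = "")
  cat(sprintf("  slopes:        a = %.6g mV (sweetness), b = %.6g mV (saltiness)\n",
              x$a, x$b))
  cat(sprintf("  sensitivities: p = %.6g, h = %.6g, q = %.6g, i = %.6g 1/mM\n",
              x$p, x$h, x$q, x$i))
  cat(sprintf("  determinant p*i - h*q = %.6g\n", x$p * x$i - x$h * x$q))
  invisible(x)
}

#' Inverse prediction-model constants
#'
#' Bundles the ten constants of the interaction-corrected inverse model that
#' predicts concentrations from the paired relative values:
#' \deqn{\hat x = j e^{F/a} + k e^{G/b} + c (e^{(F-G)/e} - 1)}
#' \deqn{\hat y = m e^{F/a} + n e^{G/b} + d (e^{(F-G)/f} - 1)}
#' The linear constants `j, k, m, n` invert the 2x2 sensitivity system of
#' the forward model; `c, e` and `d, f` parameterize exponential interaction
#' corrections that vanish whenever the two sensors agree (`F = G`). All
#' terms are additive; any sign information lives in the constants
#' themselves.
#'
#' @param a,b Sensor slopes (mV); nonzero.
#' @param j,k Linear inversion constants for acesulfame K (mM).
#' @param m,n Linear inversion constants for NaCl (mM).
#' @param c,e Interaction amplitude (mM) and decay (mV) for acesulfame K;
#'   `e` must be nonzero.
#' @param d,f Interaction amplitude (mM) and decay (mV) for NaCl; `f` must
#'   be nonzero.
#'
#' @return An object of class `inversion_params`.
#' @seealso [predict_concentrations()], [reference_inversion_params()]
#' @export
inversion_params <- function(a, b, j, k, m, n, c, d, e, f) {
  vals <- list(a = a, b = b, j = j, k = k, m = m, n = n,
               c = c, d = d, e = e, f = f)
  vals <- mapply(.check_finite_scalar, vals, names(vals), SIMPLIFY = FALSE)
  for (nm in c("a", "b", "e", "f")) {
    if (vals[[nm]] == 0) {
      stop(sprintf("'%s' must be nonzero", nm), call. = FALSE)
    }
  }
  structure(vals, class = "inversion_params")
}

#' @export
print.inversion_params <- function(x, ...) {
  cat("Inverse prediction model constants\n")
  cat(sprintf("  slopes (mV):        a = %.6g, b = %.6g\n", x$a, x$b))
  cat(sprintf("  linear (mM):        j = %.6g, k = %.6g, m = %.6g, n = %.6g\n",
              x$j, x$k, x$m, x$n))
  cat(sprintf("  interaction:        c = %.6g mM, e = %.6g mV (acesulfame K)\n",
              x$c, x$e))
  cat(sprintf("                      d = %.6g mM, f = %.6g mV (NaCl)\n",
              x$d, x$f))
  invisible(x)
}

#' Derive relative and CPA values from raw membrane potentials
#'
#' A measurement cycle records three membrane potentials: `Vr` in the
#' reference solution before the sample, `Vs` in the sample, and `Vr_after`
#' back in the reference solution after a gentle rinse. The relative value
#' is `Vs - Vr` (electrostatic plus hydrophobic contribution) and the CPA
#' value ("change in membrane potential caused by adsorption") is
#' `Vr_after - Vr`, the part that survives rinsing.
#'
#' @param Vr,Vs,Vr_after Numeric vectors of equal length (or length 1,
#'   recycled): membrane potentials in mV. All values must be finite.
#'
#' @return A [tibble][tibble::tibble] with columns `relative_mV` and
#'   `cpa_mV`, one row per measurement.
#' @examples
#' compute_outputs(Vr = 10, Vs = -40, Vr_after = -5)
#' @export
compute_outputs <- function(Vr, Vs, Vr_after) {
  args <- list(Vr = Vr, Vs = Vs, Vr_after = Vr_after)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop(sprintf("'%s' contains non-finite or non-numeric values", nm),
           call. = FALSE)
    }
  }
  n <- max(lengths(args))
  tibble::tibble(
    relative_mV = rep_len(Vs, n) - rep_len(Vr, n),
    cpa_mV = rep_len(Vr_after, n) - rep_len(Vr, n))
}

#' Forward response: concentrations to relative values
#'
#' Evaluates the logarithmic forward model at one or more mixture samples.
#' Natural logarithms are used throughout, consistent with the `exp(F/a)`
#' form of the inverse model.
#'
#' @param x Acesulfame K concentration(s), mM; nonnegative.
#' @param y NaCl concentration(s), mM; nonnegative, recycled against `x`.
#' @param params A [forward_params()] object.
#'
#' @return A [tibble][tibble::tibble] with columns `F_mV` (sweetness
#'   sensor) and `G_mV` (saltiness sensor).
#' @details In `"bare"` mode the log argument `p*x + h*y` (resp.
#'   `q*x + i*y`) must be strictly positive; a blank sample `(0, 0)` is a
#'   domain error, which is why calibration designs containing blanks are
#'   simulated and fitted in `"unit_offset"` mode.
#' @examples
#' fp <- default_forward_params()
#' forward_response(c(0, 0.25, 1), 0, fp)
#' @export
forward_response <- function(x, y, params) {
  stopifnot(inherits(params, "forward_params"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("concentrations must be finite", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  offset <- if (params$offset_mode == "unit_offset") 1 else 0
  arg_f <- offset + params$p * x + params$h * y
  arg_g <- offset + params$q * x + params$i * y
  if (params$offset_mode == "bare") {
    bad <- which(arg_f <= 0 | arg_g <= 0)
    if (length(bad)) {
      stop(sprintf(
        paste0("bare-mode log argument is <= 0 for sample(s) %s ",
               "(x = %s, y = %s); the blank cannot be modelled in bare mode"),
        paste(bad, collapse = ", "),
        paste(signif(x[bad], 6), collapse = ", "),
        paste(signif(y[bad], 6), collapse = ", ")), call. = FALSE)
    }
  }
  tibble::tibble(F_mV = params$a * log(arg_f), G_mV = params$b * log(arg_g))
}

#' Analytic linear inversion constants of the forward model
#'
#' Solves the 2x2 linear system `exp(F/a) = p*x + h*y`,
#' `exp(G/b) = q*x + i*y` for the concentrations, returning the four
#' constants `(j, k, m, n)` such that, in the additive convention of the
#' prediction model,
#' \deqn{x = j e^{F/a} + k e^{G/b}, \qquad y = m e^{F/a} + n e^{G/b}.}
#' This is the exact matrix inverse of the sensitivity matrix
#' `[[p, h], [q, i]]`: `j = i/D`, `k = -h/D`, `m = -q/D`, `n = p/D` with
#' `D = p*i - h*q`.
#'
#' @param params A [forward_params()] object with nonsingular sensitivity
#'   matrix.
#' @return A named numeric vector `c(j, k, m, n)` (mM).
#' @examples
#' fp <- forward_params(-50, -50, p = 2, h = 0, q = 0, i = 4, "bare")
#' derive_inversion_constants(fp)  # (0.5, 0, 0, 0.25)
#' @export
derive_inversion_constants <- function(params) {
  stopifnot(inherits(params, "forward_params"))
  det <- params$p * params$i - params$h * params$q
  if (!is.finite(det) || det == 0) {
    stop(sprintf("singular sensitivity matrix: determinant p*i - h*q = %g",
                 det), call. = FALSE)
  }
  c(j = params$i / det, k = -params$h / det,
    m = -params$q / det, n = params$p / det)
}

#' Exponential interaction correction term
#'
#' The correction `scale * (exp((F - G)/decay) - 1)` added to each
#' predicted concentration. It is exactly zero whenever the two sensors
#' agree (`F = G`), so it only acts on the between-sensor difference.
#'
#' @param F,G Relative values (mV); recycled to a common length.
#' @param scale Interaction amplitude (mM).
#' @param decay Interaction decay constant (mV); must be nonzero.
#' @return Numeric vector of corrections (mM).
#' @examples
#' interaction_correction(-37.2, -37.2, scale = 114.51, decay = -54.35)  # 0
#' @export
interaction_correction <- function(F, G, scale, decay) {
  scale <- .check_finite_scalar(scale, "scale")
  decay <- .check_finite_scalar(decay, "decay")
  if (decay == 0) stop("'decay' must be nonzero", call. = FALSE)
  n <- max(length(F), length(G))
  F <- rep_len(as.numeric(F), n); G <- rep_len(as.numeric(G), n)
  diff <- F - G
  out <- numeric(n)
  nz <- diff != 0  # exact zero when F == G, immune to clipping/rounding
  out[nz] <- scale * (.clipped_exp(diff[nz] / decay, "interaction") - 1)
  out
}

#' Predict concentrations from paired relative values
#'
#' Applies the full interaction-corrected inverse model to one or more
#' `(F, G)` response pairs. Estimates are returned as-is: negative values
#' are not clipped (clipping would mask fit failures) and are flagged by
#' [evaluate_predictions()] downstream.
#'
#' @param F,G Relative values (mV), recycled to a common length.
#' @param params An [inversion_params()] object.
#' @return A [tibble][tibble::tibble] with columns `x_hat_mM` (acesulfame
#'   K) and `y_hat_mM` (NaCl).
#' @examples
#' pp <- reference_inversion_params()
#' predict_concentrations(0, 0, pp)  # blank point: 0.01, -1.10 mM
#' @export
predict_concentrations <- function(F, G, params) {
  stopifnot(inherits(params, "inversion_params"))
  n <- max(length(F), length(G))
  F <- rep_len(as.numeric(F), n); G <- rep_len(as.numeric(G), n)
  if (any(!is.finite(F)) || any(!is.finite(G))) {
    stop("relative values must be finite", call. = FALSE)
  }
  ef <- .clipped_exp(F / params$a)
  eg <- .clipped_exp(G / params$b)
  x_hat <- params$j * ef + params$k * eg +
    interaction_correction(F, G, params$c, params$e)
  y_hat <- params$m * ef + params$n * eg +
    interaction_correction(F, G, params$d, params$f)
  tibble::tibble(x_hat_mM = x_hat, y_hat_mM = y_hat)
}
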