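# Synthetic two-sensor panel generator: factorial mixture designs,
# log-linear responses on the real instrument's mV scale, additive
# Gaussian measurement noise, optional raw-potential synthesis.

#' Default forward-model scenario
#'
#' A unit-offset forward model anchored to the response scale of the real
#' acesulfame K / NaCl system: slopes `a = -50.75` mV and `b = -47.6` mV,
#' with sensitivities back-solved so that the noise-free responses hit
#' `F(1 mM, 0) = -80` mV, `F(0, 50 mM) = -45` mV, `G(1 mM, 0) = -10` mV and
#' `G(0, 50 mM) = -50` mV. This reproduces the qualitative selectivity
#' picture of the instrument — the sweetness sensor responds strongly to
#' both analytes, the saltiness sensor mainly to NaCl — and is the scenario
#' used by the package's simulations. The anchor values are scenario
#' defaults chosen to look like the real system, not measured constants.
#'
#' @param F_ace1,F_nacl50 Sweetness-sensor anchors (mV): response at
#'   1 mM acesulfame K alone and at 50 mM NaCl alone.
#' @param G_ace1,G_nacl50 Saltiness-sensor anchors (mV), same two points.
#' @param a,b Sensor slopes (mV).
#' @return A [forward_params()] object in `"unit_offset"` mode.
#' @examples
#' fp <- default_forward_params()
#' forward_response(1, 0, fp)   # F = -80 mV by construction
#' @export
default_forward_params <- function(a = -50.75, b = -47.6,
                                   F_ace1 = -80, F_nacl50 = -45,
                                   G_ace1 = -10, G_nacl50 = -50) {
  # invert F = a*ln(1 + s*conc) for the sensitivity s at each anchor
  solve_s <- function(resp, slope, conc) (exp(resp / slope) - 1) / conc
  forward_params(
    a = a, b = b,
    p = solve_s(F_ace1, a, 1), h = solve_s(F_nacl50, a, 50),
    q = solve_s(G_ace1, b, 1), i = solve_s(G_nacl50, b, 50),
    offset_mode = "unit_offset")
}

#' Full factorial mixture design
#'
#' Builds the grid of two-analyte calibration samples: every combination
#' of the given acesulfame K and NaCl levels, acesulfame K as the outer
#' (slow) factor and NaCl as the inner one, with stable sample ids. The
#' standard calibration design of this system is
#' `make_design(c(0, 0.25, 0.5, 1), c(0, 10, 30, 50))` — 16 mixed samples.
#'
#' @param ace_levels Acesulfame K levels (mM), nonnegative.
#' @param nacl_levels NaCl levels (mM), nonnegative.
#' @return A [tibble][tibble::tibble] with columns `sample_id`,
#'   `taste_label`, `x_mM`, `y_mM`. The taste label classifies the sample
#'   as `"blank"`, `"acesulfame K"`, `"NaCl"` or `"mixture"`.
#' @export
make_design <- function(ace_levels, nacl_levels) {
  for (lv in list(ace_levels, nacl_levels)) {
    if (!length(lv) || !is.numeric(lv) || any(!is.finite(lv))) {
      stop("design levels must be nonempty finite numeric vectors",
           call. = FALSE)
    }
    if (any(lv < 0)) stop("design levels must be nonnegative", call. = FALSE)
  }
  grid <- expand.grid(y_mM = as.numeric(nacl_levels),
                      x_mM = as.numeric(ace_levels),
                      KEEP.OUT.ATTRS = FALSE)[, c("x_mM", "y_mM")]
  label <- function(x, y) {
    if (x == 0 && y == 0) "blank"
    else if (y == 0) "acesulfame K"
    else if (x == 0) "NaCl"
    else "mixture"
  }
  tibble::tibble(
    sample_id = sprintf("ace%g_nacl%g", grid$x_mM, grid$y_mM),
    taste_label = mapply(label, grid$x_mM, grid$y_mM),
    x_mM = grid$x_mM, y_mM = grid$y_mM)
}

#' Simulation configuration
#'
#' Collects everything a panel simulation depends on. A seed is mandatory:
#' there are no unseeded runs, so any table is exactly reproducible from
#' its configuration.
#'
#' @param design A design tibble from [make_design()] (columns `sample_id`,
#'   `x_mM`, `y_mM`, optionally `taste_label`).
#' @param params A [forward_params()] object; defaults to
#'   [default_forward_params()].
#' @param noise_sd Additive Gaussian measurement noise on each relative
#'   value, in mV; nonnegative. Default 1 mV, a conservative fraction of
#'   the 50-80 mV signals.
#' @param n_replicates Replicate measurements per sample; at least 1.
#' @param seed Integer seed; required.
#' @param emit_raw If `TRUE`, also synthesize raw membrane potentials
#'   (`Vr`, `Vs`, `Vr_after`) consistent with [compute_outputs()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(design, params = default_forward_params(),
                              noise_sd = 1, n_replicates = 1, seed,
                              emit_raw = FALSE) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required: unseeded simulations are not reproducible",
         call. = FALSE)
  }
  seed <- .check_finite_scalar(seed, "seed")
  stopifnot(inherits(params, "forward_params"),
            is.data.frame(design),
            all(c("sample_id", "x_mM", "y_mM") %in% names(design)))
  noise_sd <- .check_finite_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  n_replicates <- .check_finite_scalar(n_replicates, "n_replicates")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(
    list(design = tibble::as_tibble(design), params = params,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed), emit_raw = isTRUE(emit_raw)),
    class = "simulation_config")
}

#' Simulate a two-sensor panel table
#'
#' For every design sample and replicate, draws the sweetness and
#' saltiness relative values from the forward model plus independent
#' Gaussian noise, and returns them as a tidy long-format panel (one row
#' per sample x sensor x replicate). With `emit_raw = TRUE` the raw
#' potentials are synthesized so that `Vs - Vr` reproduces the stored
#' relative value exactly, with `Vr` drawn near 0 mV and the CPA value set
#' to 20% of the relative value (the relative value of this sensor family
#' runs several times higher than its CPA value).
#'
#' @param config A [simulation_config()] object.
#' @return A panel [tibble][tibble::tibble] with columns `sample_id`,
#'   `taste_label`, `x_mM`, `y_mM`, `sensor_id`, `replicate`,
#'   `relative_mV` and, if requested, `Vr_mV`, `Vs_mV`, `Vr_after_mV`,
#'   `cpa_mV`.
#' @examples
#' cfg <- simulation_config(make_design(c(0, 0.25, 0.5, 1), c(0, 10, 30, 50)),
#'                          noise_sd = 1, n_replicates = 4, seed = 42)
#' panel <- simulate_panel(cfg)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  des <- config$design
  if (!"taste_label" %in% names(des)) des$taste_label <- "mixture"
  resp <- forward_response(des$x_mM, des$y_mM, config$params)
  n_samp <- nrow(des)
  reps <- config$n_replicates

  long_one <- function(sensor_id, clean) {
    tibble::tibble(
      sample_id = rep(des$sample_id, each = reps),
      taste_label = rep(des$taste_label, each = reps),
      x_mM = rep(des$x_mM, each = reps),
      y_mM = rep(des$y_mM, each = reps),
      sensor_id = sensor_id,
      replicate = rep(seq_len(reps), times = n_samp),
      clean_mV = rep(clean, each = reps))
  }
  panel <- rbind(long_one("sweetness", resp$F_mV),
                 long_one("saltiness", resp$G_mV))

  set.seed(config$seed)
  panel$relative_mV <- panel$clean_mV +
    stats::rnorm(nrow(panel), mean = 0, sd = config$noise_sd)
  panel$clean_mV <- NULL
  if (config$emit_raw) {
    panel$Vr_mV <- stats::rnorm(nrow(panel), mean = 0, sd = 0.5)
    panel$Vs_mV <- panel$Vr_mV + panel$relative_mV
    panel$Vr_after_mV <- panel$Vr_mV + 0.2 * panel$relative_mV
    # re-derive the outputs from the stored potentials so that
    # compute_outputs(raw columns) reproduces them bit-exactly
    outs <- compute_outputs(panel$Vr_mV, panel$Vs_mV, panel$Vr_after_mV)
    panel$relative_mV <- outs$relative_mV
    panel$cpa_mV <- outs$cpa_mV
    panel <- panel[, c("sample_id", "taste_label", "x_mM", "y_mM",
                       "sensor_id", "replicate", "Vr_mV", "Vs_mV",
                       "Vr_after_mV", "relative_mV", "cpa_mV")]
  }
  tibble::as_tibble(panel)
}

#' Reshape a long panel into a calibration table
#'
#' Joins the two sensors of each (sample, replicate) pair into one row
#' with the sweetness response `F_mV` and saltiness response `G_mV`
#' side by side — the layout the fitting routines consume.
#'
#' @param panel A long-format panel tibble (from [simulate_panel()] or
#'   [read_panel()]).
#' @return A [tibble][tibble::tibble] with columns `sample_id`, `x_mM`,
#'   `y_mM`, `replicate`, `F_mV`, `G_mV`.
#' @export
as_calibration_table <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("sample_id", "x_mM", "y_mM", "sensor_id", "replicate",
                  "relative_mV") %in% names(panel)))
  bad <- setdiff(unique(panel$sensor_id), c("sweetness", "saltiness"))
  if (length(bad)) {
    stop(sprintf("unknown sensor id(s): %s (known: sweetness, saltiness)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sweet <- panel[panel$sensor_id == "sweetness",
                 c("sample_id", "x_mM", "y_mM", "replicate", "relative_mV")]
  salty <- panel[panel$sensor_id == "saltiness",
                 c("sample_id", "replicate", "relative_mV")]
  names(sweet)[names(sweet) == "relative_mV"] <- "F_mV"
  names(salty)[names(salty) == "relative_mV"] <- "G_mV"
  out <- dplyr::inner_join(sweet, salty, by = c("sample_id", "replicate"))
  if (nrow(out) == 0) {
    stop("panel has no (sample, replicate) pair measured by both sensors",
         call. = FALSE)
  }
  tibble::as_tibble(out[order(out$sample_id, out$replicate), ])
}
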