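# CSV panel reader/writer, flat key=value parameter files, scenario
# configuration. All files are plain text: RFC-4180 CSV with '.' decimal
# separator, UTF-8, numeric values serialized at 10 significant digits.

.PANEL_SCHEMA <- "etongue-panel v1"
.PARAMS_SCHEMA <- "etongue-params v1"
.PARAM_KEYS <- c("a", "b", "j", "k", "m", "n", "c", "d", "e", "f")
.PARAM_UNITS <- c(a = "mV", b = "mV", j = "mM", k = "mM", m = "mM",
                  n = "mM", c = "mM", d = "mM", e = "mV", f = "mV")

#' Write a panel table to CSV
#'
#' Serializes a long-format panel as RFC-4180 CSV with a `# schema`
#' comment line; numeric columns are rounded to 10 significant digits, so
#' `read_panel(write_panel(x))` reproduces the written values bit-exactly.
#'
#' @param panel Panel tibble (see [simulate_panel()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  out <- panel
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 10)
  }
  writeLines(paste0("# ", .PANEL_SCHEMA), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a panel table from CSV
#'
#' Reads and validates a long-format panel. When raw potential columns
#' (`Vr_mV`, `Vs_mV`) are present, the derived columns are reconciled via
#' [compute_outputs()]: a missing `relative_mV` is filled in as
#' `Vs - Vr`, and a stored `relative_mV` that disagrees with the raw
#' potentials by more than 1e-6 mV is an error.
#'
#' @param path CSV file with a header; `#` lines are comments. Required
#'   columns: `sample_id`, `sensor_id`, and `relative_mV` or
#'   (`Vr_mV`, `Vs_mV`). A missing `replicate` column defaults to 1.
#' @return A validated panel [tibble][tibble::tibble].
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(panel)
  if (nrow(probs) > 0) {
    stop(sprintf("could not parse '%s': %s at row %d, column %d",
                 path, probs$expected[1], probs$row[1], probs$col[1]),
         call. = FALSE)
  }
  miss <- setdiff(c("sample_id", "sensor_id"), names(panel))
  if (length(miss)) {
    stop(sprintf("panel file is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"replicate" %in% names(panel)) panel$replicate <- 1L
  has_raw <- all(c("Vr_mV", "Vs_mV") %in% names(panel))
  if (!has_raw && !"relative_mV" %in% names(panel)) {
    stop("panel file needs 'relative_mV' or raw columns 'Vr_mV' and 'Vs_mV'",
         call. = FALSE)
  }
  num_cols <- intersect(
    c("x_mM", "y_mM", "Vr_mV", "Vs_mV", "Vr_after_mV", "relative_mV",
      "cpa_mV"), names(panel))
  for (col in num_cols) {
    if (!is.numeric(panel[[col]])) {
      bad <- which(!is.na(panel[[col]]) &
                     is.na(suppressWarnings(as.numeric(panel[[col]]))))[1]
      stop(sprintf("non-numeric value in column '%s' (data row %s)",
                   col, ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
  }
  key <- paste(panel$sample_id, panel$sensor_id, panel$replicate, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop(sprintf("duplicated (sample_id, sensor_id, replicate) key(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (has_raw) {
    vr_after <- if ("Vr_after_mV" %in% names(panel)) panel$Vr_after_mV
                else panel$Vr_mV  # cpa undefined without Vr'; yields 0
    outs <- compute_outputs(panel$Vr_mV, panel$Vs_mV, vr_after)
    if ("relative_mV" %in% names(panel)) {
      dev <- abs(panel$relative_mV - outs$relative_mV)
      if (any(dev > 1e-6)) {
        stop(sprintf(
          paste("'relative_mV' conflicts with Vs - Vr by up to %g mV",
                "(first at data row %d)"),
          max(dev), which(dev > 1e-6)[1]), call. = FALSE)
      }
    } else {
      panel$relative_mV <- outs$relative_mV
    }
    if ("Vr_after_mV" %in% names(panel) && !"cpa_mV" %in% names(panel)) {
      panel$cpa_mV <- outs$cpa_mV
    }
  }
  tibble::as_tibble(panel)
}

#' Write model constants to a flat parameter file
#'
#' `key = value` lines with the unit of each constant in a trailing
#' comment; values carry full double precision, so
#' `read_params(write_params(p))` is exact.
#'
#' @param params An [inversion_params()] object or a `fit_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "fit_result")) params <- params$params
  stopifnot(inherits(params, "inversion_params"))
  lines <- c(
    paste0("# ", .PARAMS_SCHEMA),
    "# inverse prediction model constants",
    sprintf("%s = %s  # %s", .PARAM_KEYS,
            vapply(.PARAM_KEYS,
                   function(k) formatC(params[[k]], digits = 17,
                                       format = "g"),
                   character(1)),
            .PARAM_UNITS[.PARAM_KEYS]))
  writeLines(lines, path)
  invisible(path)
}

#' Read model constants from a flat parameter file
#'
#' @param path A file written by [write_params()] (or edited by hand):
#'   `key = value` lines, `#` comments ignored. All ten keys
#'   `a b j k m n c d e f` must be present exactly once.
#' @return An [inversion_params()] object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop(sprintf("malformed parameter line: '%s'", lines[bad][1]),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`,
                                                    character(1), 2))))
  unknown <- setdiff(keys, .PARAM_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown parameter key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing_keys <- setdiff(.PARAM_KEYS, keys)
  if (length(missing_keys)) {
    stop(sprintf("missing parameter key(s): %s",
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicated parameter key(s): %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(vals))) {
    stop(sprintf("non-finite value for key(s): %s",
                 paste(keys[!is.finite(vals)], collapse = ", ")),
         call. = FALSE)
  }
  names(vals) <- keys
  do.call(inversion_params, as.list(vals[.PARAM_KEYS]))
}

#' Published reference constants for the acesulfame K / NaCl system
#'
#' Loads the packaged parameter file holding the ten inverse-model
#' constants reported for a laboratory calibration of this sensor pair on
#' the 16-sample acesulfame K x NaCl factorial design
#' (a = -50.75 mV, b = -47.6 mV, j = 0.50 mM, k = -0.49 mM,
#' m = -177.45 mM, n = 176.35 mM, c = -0.024 mM, d = 114.51 mM,
#' e = -16.92 mV, f = -54.35 mV). Useful as a worked example and as a
#' plausibility anchor for simulated fits.
#'
#' @return An [inversion_params()] object.
#' @examples
#' predict_concentrations(0, 0, reference_inversion_params())
#' @export
reference_inversion_params <- function() {
  read_params(system.file("extdata", "acesulfame_nacl_constants.txt",
                          package = "etongue", mustWork = TRUE))
}

#' Read a simulation scenario file
#'
#' YAML scenario with optional keys `ace_levels`, `nacl_levels`,
#' `noise_sd`, `n_replicates`, `emit_raw`, and an optional `forward`
#' block (`a b p h q i offset_mode`) overriding
#' [default_forward_params()]. The seed is deliberately not part of the
#' scenario: it is supplied per run.
#'
#' @param path YAML file.
#' @param seed Integer seed for the run.
#' @return A [simulation_config()] object.
#' @export
read_scenario <- function(path, seed) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_scenario requires the 'yaml' package", call. = FALSE)
  }
  sc <- yaml::read_yaml(path)
  params <- if (!is.null(sc$forward)) {
    do.call(forward_params, sc$forward)
  } else {
    default_forward_params()
  }
  num <- function(v) as.numeric(unlist(v))  # YAML may type levels as a list
  design <- make_design(
    ace_levels = num(sc$ace_levels %||% c(0, 0.25, 0.5, 1)),
    nacl_levels = num(sc$nacl_levels %||% c(0, 10, 30, 50)))
  simulation_config(
    design = design, params = params,
    noise_sd = sc$noise_sd %||% 1,
    n_replicates = sc$n_replicates %||% 1,
    seed = seed,
    emit_raw = isTRUE(sc$emit_raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a prediction report to CSV
#'
#' The per-sample predictions go into the CSV body; the pooled metrics
#' are recorded as `# key = value` comment lines above the header.
#'
#' @param report A `prediction_report` from [evaluate_predictions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "prediction_report"))
  writeLines(c(
    "# etongue-report v1",
    sprintf("# r2_x = %.10g", report$r2_x),
    sprintf("# r2_y = %.10g", report$r2_y),
    sprintf("# rmse_x_mM = %.10g", report$rmse_x),
    sprintf("# rmse_y_mM = %.10g", report$rmse_y)), path)
  out <- report$predictions
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 10)
  }
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
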