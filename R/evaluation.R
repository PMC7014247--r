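# Metrics and reports: predicted-vs-actual concentration tables, R^2 and
# RMSE, and the per-taste selectivity summary of a panel.

#' Coefficient of determination of predicted vs actual values
#'
#' `1 - sum((predicted - actual)^2) / sum((actual - mean(actual))^2)`,
#' pooled over all points — the predicted-versus-actual framing used for
#' calibration quality in this field. Can be negative for predictors
#' worse than the mean.
#'
#' @param actual,predicted Numeric vectors of equal length (>= 2);
#'   `actual` must not be constant.
#' @return A single number <= 1.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 1))  # 0.5
#' @export
r_squared <- function(actual, predicted) {
  stopifnot(is.numeric(actual), is.numeric(predicted))
  if (length(actual) != length(predicted)) {
    stop("'actual' and 'predicted' must have the same length", call. = FALSE)
  }
  if (length(actual) < 2) {
    stop("need at least two points", call. = FALSE)
  }
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) {
    stop("'actual' values are all identical: variance is undefined",
         call. = FALSE)
  }
  1 - sum((predicted - actual)^2) / ss_tot
}

#' Evaluate an inverse model on a table of known mixtures
#'
#' Applies [predict_concentrations()] to every row of a calibration table
#' and summarizes the agreement between estimated and actual
#' concentrations. Estimates that are negative or exceed twice the
#' table's maximum true level are flagged (not altered): a well-behaved
#' fit of this model can leave a small negative blank-equivalent
#' intercept, so out-of-range values are a warning sign, not an error.
#'
#' @param table Calibration table with columns `x_mM`, `y_mM`, `F_mV`,
#'   `G_mV` (and optionally `sample_id`).
#' @param params An [inversion_params()] object (or a `fit_result`, whose
#'   parameters are used).
#' @return An object of class `prediction_report`: a `predictions` tibble
#'   (`sample_id`, `x_true_mM`, `x_hat_mM`, `y_true_mM`, `y_hat_mM`,
#'   `flag`) plus `r2_x`, `r2_y`, `rmse_x`, `rmse_y`.
#' @export
evaluate_predictions <- function(table, params) {
  if (inherits(params, "fit_result")) params <- params$params
  stopifnot(inherits(params, "inversion_params"))
  .check_calibration_table(table)
  if (nrow(table) == 0) stop("empty calibration table", call. = FALSE)
  pred <- predict_concentrations(table$F_mV, table$G_mV, params)
  x_max <- max(table$x_mM); y_max <- max(table$y_mM)
  flag_one <- function(est, max_level, analyte) {
    ifelse(est < 0, paste0("negative_", analyte),
           ifelse(est > 2 * max_level & max_level > 0,
                  paste0("high_", analyte), ""))
  }
  fx <- flag_one(pred$x_hat_mM, x_max, "x")
  fy <- flag_one(pred$y_hat_mM, y_max, "y")
  flag <- trimws(paste(fx, fy))
  predictions <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(table)) table$sample_id
                else sprintf("row%d", seq_len(nrow(table))),
    x_true_mM = table$x_mM, x_hat_mM = pred$x_hat_mM,
    y_true_mM = table$y_mM, y_hat_mM = pred$y_hat_mM,
    flag = flag)
  structure(
    list(predictions = predictions,
         r2_x = r_squared(predictions$x_true_mM, predictions$x_hat_mM),
         r2_y = r_squared(predictions$y_true_mM, predictions$y_hat_mM),
         rmse_x = sqrt(mean((predictions$x_hat_mM -
                               predictions$x_true_mM)^2)),
         rmse_y = sqrt(mean((predictions$y_hat_mM -
                               predictions$y_true_mM)^2))),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  n_flag <- sum(nzchar(x$predictions$flag))
  cat(sprintf("Prediction report: %d samples, %d flagged\n",
              nrow(x$predictions), n_flag))
  cat(sprintf("  acesulfame K: R^2 = %.4f, RMSE = %.4g mM\n",
              x$r2_x, x$rmse_x))
  cat(sprintf("  NaCl:         R^2 = %.4f, RMSE = %.4g mM\n",
              x$r2_y, x$rmse_y))
  print(x$predictions, n = 8)
  invisible(x)
}

#' Selectivity summary of a panel
#'
#' Per (sensor, taste sample) mean and standard deviation of the relative
#' value — the tabular analogue of a selectivity bar chart. No
#' thresholding or classification is applied; the table simply shows how
#' strongly each sensor responds to each taste sample.
#'
#' @param panel Long-format panel tibble with columns `sensor_id`,
#'   `taste_label`, `relative_mV`.
#' @return A [tibble][tibble::tibble] with columns `sensor_id`,
#'   `taste_label`, `n`, `mean_mV`, `sd_mV` (0 when a cell has a single
#'   observation).
#' @export
selectivity_table <- function(panel) {
  stopifnot(is.data.frame(panel))
  need <- c("sensor_id", "taste_label", "relative_mV")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop(sprintf("panel is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  known <- c("sweetness", "saltiness")
  bad <- setdiff(unique(panel$sensor_id), known)
  if (length(bad)) {
    stop(sprintf("unknown sensor id(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")),
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(panel, .data$sensor_id, .data$taste_label),
    n = dplyr::n(),
    mean_mV = mean(.data$relative_mV),
    sd_mV = ifelse(dplyr::n() > 1, stats::sd(.data$relative_mV), 0),
    .groups = "drop")
  tibble::as_tibble(out)
}

#' Scatter plot of estimated vs actual concentrations
#'
#' One panel per analyte, with the identity line; points are the rows of
#' the prediction report.
#'
#' @param report A `prediction_report` from [evaluate_predictions()].
#' @param path Optional file path; if given, the plot is saved there
#'   (format from the extension) and the ggplot object returned
#'   invisibly.
#' @return A ggplot object.
#' @export
plot_predictions <- function(report, path = NULL) {
  stopifnot(inherits(report, "prediction_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_predictions requires the 'ggplot2' package", call. = FALSE)
  }
  pr <- report$predictions
  long <- rbind(
    data.frame(analyte = "acesulfame K (mM)", actual = pr$x_true_mM,
               estimated = pr$x_hat_mM),
    data.frame(analyte = "NaCl (mM)", actual = pr$y_true_mM,
               estimated = pr$y_hat_mM))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$actual, .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~analyte, scales = "free") +
    ggplot2::labs(x = "actual concentration",
                  y = "estimated concentration") +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 3.5)
    return(invisible(p))
  }
  p
}
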