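#' Bland-Altman plot
#'
#' Pairwise differences (measured minus predicted) against pairwise means,
#' with the bias line and the 1.96-SD limits of agreement.
#'
#' @param object An `ee_bland_altman` result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ee_bland_altman <- function(object, ...) {
  pts <- attr(object, "points")
  if (is.null(pts)) stop("result carries no point data", call. = FALSE)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "Mean of measured and predicted EE (kcal/window)",
      y = "Measured - predicted (kcal)",
      title = sprintf("Bland-Altman agreement (%.1f%% within limits)",
                      object$pct_within)
    ) +
    ggplot2::theme_minimal()
}

#' Hidden-node search error curve
#'
#' Held-out RMSE against candidate hidden-node count, marking the selected
#' minimum.
#'
#' @param object An `ee_node_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ee_node_search <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$n_hidden, y = .data$rmse)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = res[res$n_hidden == object$best, ],
                        colour = "firebrick", size = 3) +
    ggplot2::scale_x_continuous(breaks = res$n_hidden) +
    ggplot2::labs(x = "Hidden nodes", y = "Held-out RMSE (kcal)",
                  title = sprintf("Hidden-node search (best = %d)",
                                  object$best)) +
    ggplot2::theme_minimal()
}

#' Per-stage MAPE bars
#'
#' Stage-wise MAPE per model with the 15% reasonable-error reference line.
#'
#' @param report An `ee_validation_report`.
#' @param threshold Reference line in percent.
#' @return A ggplot.
#' @export
plot_stage_mape <- function(report, threshold = 15) {
  stopifnot(inherits(report, "ee_validation_report"))
  ggplot2::ggplot(report$by_stage,
                  ggplot2::aes(x = factor(.data$stage_index), y = .data$mape,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Stage", y = "MAPE (%)", fill = "Model",
                  title = "Per-stage prediction error") +
    ggplot2::theme_minimal()
}

#' Predicted against measured EE series
#'
#' @param report An `ee_validation_report`.
#' @return A ggplot of predicted vs measured kcal per window, per model.
#' @export
plot_predicted_measured <- function(report) {
  stopifnot(inherits(report, "ee_validation_report"))
  ggplot2::ggplot(report$predictions,
                  ggplot2::aes(x = .data$measured, y = .data$predicted,
                               colour = .data$period)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::facet_wrap(~ .data$model) +
    ggplot2::labs(x = "Measured EE (kcal/window)",
                  y = "Predicted EE (kcal/window)", colour = "Period") +
    ggplot2::theme_minimal()
}

#' Training error history
#'
#' @param model A fitted `ee_bpnn`.
#' @return A ggplot of scaled MSE by epoch.
#' @export
plot_training_history <- function(model) {
  stopifnot(inherits(model, "ee_bpnn"))
  h <- tibble(epoch = seq_along(model$history), mse = model$history)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Scaled MSE") +
    ggplot2::theme_minimal()
}
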