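# ggplot2 displays for the main result types.

#' Plot the Calinski-Harabasz curve of a habitat-count selection
#'
#' @param ch_by_k tibble with `k` and `ch` (from [select_k()] or a
#'   `habitat_report`).
#' @return a ggplot.
#' @export
plot_ch_curve <- function(ch_by_k) {
  if (inherits(ch_by_k, "habitat_report")) ch_by_k <- ch_by_k$ch_by_k
  ggplot2::ggplot(ch_by_k, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "number of habitats k", y = "Calinski-Harabasz index") +
    ggplot2::theme_minimal()
}

#' ROC curves for one or more scores
#'
#' @param scores named list of score vectors (or a single vector).
#' @param outcome 0/1 outcome vector.
#' @return a ggplot of ROC curves with AUC labels.
#' @export
plot_roc <- function(scores, outcome) {
  if (!is.list(scores)) scores <- list(score = scores)
  df <- dplyr::bind_rows(lapply(names(scores), function(nm) {
    rc <- roc_curve(scores[[nm]], outcome)
    auc <- evaluate_model(scores[[nm]], outcome)$auc
    dplyr::mutate(rc, model = sprintf("%s (AUC %.3f)", nm, auc))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity,
                                   colour = .data$model)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' AUC summary plot of a pipeline report
#'
#' @param object a `habitat_report`.
#' @param ... unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.habitat_report <- function(object, ...) {
  ev <- object$evaluation
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$model, y = .data$auc,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "AUC (95% CI)", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration plot
#'
#' @param calib tibble from [calibration_curve()].
#' @return a ggplot.
#' @export
plot_calibration <- function(calib) {
  ggplot2::ggplot(calib, ggplot2::aes(x = .data$mean_predicted,
                                      y = .data$observed_rate)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted probability", y = "observed rate") +
    ggplot2::theme_minimal()
}

#' Decision-curve plot
#'
#' @param dca tibble from [decision_curve()].
#' @return a ggplot of net benefit against threshold probability.
#' @export
plot_decision_curve <- function(dca) {
  long <- tidyr::pivot_longer(dca, c("net_benefit", "treat_all", "treat_none"),
                              names_to = "policy", values_to = "nb")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                     colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.1, max(long$nb) + 0.05)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit", colour = NULL) +
    ggplot2::theme_minimal()
}
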