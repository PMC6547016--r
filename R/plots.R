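#' Plot an evaluation report
#'
#' @param object An `ews_evaluation` from [evaluate_score()].
#' @param type One of `"roc"`, `"pr"`, `"efficiency"`, `"auroc_window"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ews_evaluation <- function(object, type = c("roc", "pr", "efficiency",
                                                     "auroc_window"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    ggplot2::ggplot(object$roc_curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("%s  AUROC %.3f (%.3f-%.3f)",
                                    object$score_name, object$auroc,
                                    object$ci_low, object$ci_high)) +
      ggplot2::coord_equal()
  } else if (type == "pr") {
    ggplot2::ggplot(object$pr_curve, ggplot2::aes(x = .data$recall,
                                                  y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Sensitivity (recall)", y = "PPV (precision)",
                    title = paste("Precision-recall:", object$score_name))
  } else if (type == "efficiency") {
    ggplot2::ggplot(object$efficiency_curve,
                    ggplot2::aes(x = .data$obs_fraction,
                                 y = .data$event_fraction)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Fraction of observations alerting",
                    y = "Fraction of event observations captured",
                    title = paste("Efficiency curve:", object$score_name))
  } else {
    if (is.null(object$auroc_by_window)) {
      stop_input("report carries no AUROC-by-window curve")
    }
    ggplot2::ggplot(dplyr::filter(object$auroc_by_window, !is.na(.data$auroc)),
                    ggplot2::aes(x = .data$window_h, y = .data$auroc)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "Time-to-event window (hours)", y = "AUROC",
                    title = paste("Discrimination approaching the event:",
                                  object$score_name))
  }
}

#' Plot derived FiO2 bands
#'
#' Per-band event rates with band widths on the FiO2 axis, a visual check
#' that risk increases with the inspired oxygen fraction.
#'
#' @param object A `fio2_band_fit` from [derive_fio2_bands()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fio2_band_fit <- function(object, ...) {
  s <- object$band_summary
  ggplot2::ggplot(s, ggplot2::aes(xmin = 100 * .data$fio2_low,
                                  xmax = 100 * .data$fio2_high,
                                  ymin = 0, ymax = .data$event_rate,
                                  fill = factor(.data$weight))) +
    ggplot2::geom_rect(colour = "white") +
    ggplot2::labs(x = "Calculated FiO2 (%)", y = "Event rate",
                  fill = "Band weight",
                  title = "Event rate by derived FiO2 band")
}
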