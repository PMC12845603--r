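# ggplot2 displays for the main result types.

#' Plot subjective ratings across stress conditions
#'
#' Box-and-whisker of pooled block ratings per condition, with one line per
#' subject across the protocol order.
#'
#' @param study A stress-study tibble (`subject_id`, `condition`, `rating`).
#' @return A ggplot object.
#' @export
plot_ratings <- function(study) {
  d <- study |> distinct(.data$subject_id, .data$condition, .data$rating)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$rating)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id,
                                    colour = .data$subject_id),
                       alpha = 0.5, show.legend = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$subject_id),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(1, 9), breaks = 1:9) +
    ggplot2::labs(x = NULL, y = "subjective stress rating (1-9)") +
    ggplot2::theme_minimal()
}

#' Per-fold metric bars for a cross-validation result
#'
#' @param object An `eeg_cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_cv_result <- function(object, ...) {
  metric_cols <- setdiff(names(object$folds), c("fold", "n_train", "n_val"))
  d <- object$folds |>
    pivot_longer(all_of(metric_cols), names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Beeswarm-style attribution summary plot
#'
#' Per-feature scatter of per-instance Shapley values, coloured by the
#' min-max-normalized feature magnitude (blue = -1, white = 0, red = +1).
#'
#' @param bees Output of [shap_beeswarm_data()].
#' @return A ggplot object.
#' @export
autoplot_beeswarm <- function(bees) {
  ggplot2::ggplot(bees, ggplot2::aes(x = .data$phi, y = .data$feature,
                                     colour = .data$value_norm)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1, alpha = 0.8) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white", high = "red",
                                    limits = c(-1, 1), name = "feature value") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Shapley value", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot median sigmoid outputs across difficulty levels
#'
#' @param med Output of [median_sigmoid_by_session()].
#' @return A ggplot object.
#' @export
plot_median_sigmoid <- function(med) {
  ggplot2::ggplot(med, ggplot2::aes(x = .data$level, y = .data$median_prob)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$subject_id, .data$session),
                                    colour = .data$subject_id),
                       alpha = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = "mental workload level", y = "median sigmoid output") +
    ggplot2::theme_minimal()
}
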