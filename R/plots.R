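#' Plot a detection report
#'
#' Bar panel of the four sensitivity/selectivity metrics plus the composite
#' surveillance score for one profile.
#'
#' @param object A [detection_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.detection_report <- function(object, ...) {
  df <- tidy(object)
  df$metric <- factor(df$metric, levels = df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Detection accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the mapping-error modelling grid
#'
#' Heat map of each metric variant over the cross of true-taxa-detected by
#' false-positive-taxa-detected, the view that exposes which variants
#' respond proportionately to both error sources.
#'
#' @param object A [modelling_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modelling_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              -c("n_true_detected", "n_false_positive"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("SAE", "nSAE", "wnSAE", "RMSE", "nRMSE", "wnRMSE"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_false_positive,
                                     y = .data$n_true_detected,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "false-positive taxa detected",
                  y = "true taxa detected",
                  fill = "error") +
    ggplot2::theme_minimal()
}

#' Stacked FN/FP decomposition of mapping errors
#'
#' Shows, for each metric row of a mapping-error report, how much of the
#' error value derives from under-detection (false negatives) versus
#' over-detection (false positives). For the SAE family the two bars stack
#' exactly to the metric value (the weighted FN component times the weight
#' plus the FP component).
#'
#' @param report A `mapping_error_report` (one or more rows, e.g. from
#'   [mapping_error_all()]).
#' @return A ggplot object.
#' @export
plot_error_decomposition <- function(report) {
  df <- as_tibble(report) |>
    dplyr::filter(.data$metric %in% c("SAE", "nSAE", "wnSAE")) |>
    dplyr::mutate(`false-negative derived` = .data$weight_w * .data$fn_component,
                  `false-positive derived` = .data$fp_component) |>
    tidyr::pivot_longer(c("false-negative derived", "false-positive derived"),
                        names_to = "source", values_to = "error")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$error,
                                   fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("false-negative derived" = "forestgreen",
                                          "false-positive derived" = "firebrick")) +
    ggplot2::labs(x = NULL, y = "error (percent-abundance scale)", fill = NULL) +
    ggplot2::theme_minimal()
}
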