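#' Plot the event-class composition of classified clusters
#'
#' @param events events tibble from [classify_clusters()].
#' @return a ggplot.
#' @export
plot_event_classes <- function(events) {
  d <- events %>%
    dplyr::mutate(type = sub("\\(\\d+\\)$", "", .data$event_type)) %>%
    dplyr::count(.data$type)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$type, -.data$n),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "event class", y = "clusters",
                  title = "Splice-junction cluster classification") +
    ggplot2::theme_minimal()
}

#' Plot retained introns per retention-ratio bin
#'
#' @param ir retained-intron tibble from [classify_clusters()].
#' @return a ggplot.
#' @export
plot_irr_bins <- function(ir) {
  d <- ir %>% dplyr::count(.data$irr_bin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$irr_bin, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "intron retention ratio bin", y = "retained introns") +
    ggplot2::theme_minimal()
}

#' Boxplot of an intron feature by class
#'
#' @param features tibble from [compute_features()].
#' @param feature_name one of length, gc, five_score, three_score,
#'   branch_score.
#' @return a ggplot.
#' @export
plot_feature_by_class <- function(features, feature_name = "length") {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$cls, y = .data[[feature_name]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::labs(x = NULL, y = feature_name) +
    ggplot2::theme_minimal()
}

#' Scatter of log isoform-frequency ratio against score difference
#'
#' @param x an `isoform_regressions` object from [isoform_stats()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.isoform_regressions <- function(x, ...) {
  d <- x$isoforms %>%
    dplyr::filter(!is.na(.data$log_freq_ratio), !is.na(.data$delta_score))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_score,
                                  y = .data$log_freq_ratio)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_wrap(~pair_type, scales = "free") +
    ggplot2::labs(x = "splice-site score difference (bits)",
                  y = "ln(isoform frequency ratio)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a site log-odds matrix
#'
#' @param x a `pwm` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pwm <- function(x, ...) {
  d <- tidy.pwm(x)
  d$log_odds[!is.finite(d$log_odds)] <- NA
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$base,
                                  fill = .data$log_odds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", high = "firebrick",
                                  na.value = "grey40") +
    ggplot2::labs(x = "position", y = NULL, fill = "bits") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
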