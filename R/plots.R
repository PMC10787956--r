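# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.psd_estimate <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (mV²/Hz)",
                  title = sprintf("Welch PSD (%d segments)",
                                  object$n_segments)) +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of relative band power
#'
#' Group mean with standard-error bars per band and channel — the classic
#' band-power comparison figure.
#'
#' @param features Feature tibble from [extract_features()] (or a
#'   `bruxism_report$features`).
#' @return A ggplot object.
#' @export
plot_rpsd_profile <- function(features) {
  df <- rpsd_summary(features)
  df$band <- factor(df$band, levels = c("delta", "theta", "alpha", "beta"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = NULL, y = "Relative band power (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tree_cv <- function(object, ...) {
  df <- tibble::tibble(metric = factor(names(object$metrics),
                                       levels = names(object$metrics)),
                       value = unname(object$metrics))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "Percent",
                  title = sprintf("Pooled %d-fold CV", object$k)) +
    ggplot2::theme_minimal()
}

#' Significance overview of the feature screen
#'
#' -log10 p-value per feature and channel, with the significance
#' threshold drawn as a horizontal line.
#'
#' @param sig A `significance_table` from [compare_groups()].
#' @param alpha Significance level to mark (default 0.05).
#' @return A ggplot object.
#' @export
plot_feature_significance <- function(sig, alpha = 0.05) {
  df <- dplyr::filter(sig, !is.na(.data$p_value))
  df$feature <- factor(df$feature, levels = feature_names())
  df$neglogp <- -log10(pmax(df$p_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$neglogp)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
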