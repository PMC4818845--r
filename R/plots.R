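#' Plot a binned frequency profile
#'
#' Scatter of per-bin mean metric against per-bin mean contact frequency with
#' a least-squares trend line, the usual way binned TE-density profiles are
#' displayed.
#'
#' @param bins Output of [bin_by_frequency()].
#' @param metric_name Axis label for the metric.
#' @return A ggplot object.
#' @export
plot_frequency_profile <- function(bins, metric_name = "mean metric") {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_frequency,
                                     y = .data$mean_metric)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.4) +
    ggplot2::labs(x = "mean contact frequency (per bin)", y = metric_name) +
    ggplot2::theme_minimal()
}

#' Plot a TE family correlation profile
#'
#' Bar chart of binned Pearson r per selector, annotated with significance.
#'
#' @param profile Output of [family_profile()] (optionally with a `stratum`
#'   column).
#' @return A ggplot object.
#' @export
plot_family_profile <- function(profile) {
  d <- profile[!profile$absent, , drop = FALSE]
  d$selector <- factor(d$selector, levels = unique(profile$selector))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$selector, y = .data$r,
                                       fill = .data$p < 0.01)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               name = "p < 0.01") +
    ggplot2::labs(x = NULL, y = "binned Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("stratum" %in% names(d)) p <- p + ggplot2::facet_wrap(~stratum)
  p
}

#' @rdname plot_enrichment
#' @export
autoplot.ci_enrichtest <- function(object, ...) plot_enrichment(object, ...)

#' Plot a coverage enrichment test
#'
#' Background coverage distribution with the observed and background means
#' marked.
#'
#' @param x A `ci_enrichtest` object; needs the raw background vector passed
#'   as `background`.
#' @param background Numeric vector of background coverages.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x, background = NULL, ...) {
  d <- tibble::tibble(coverage = background %||% numeric())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coverage)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey80", colour = "grey50") +
    ggplot2::geom_vline(xintercept = x$background_mean, colour = "grey30",
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = x$observed_mean, colour = "firebrick") +
    ggplot2::labs(x = "Alu coverage per window", y = "background windows",
                  subtitle = sprintf("binomial p = %.3g (k = %d / n = %d)",
                                     x$p_value, x$k_above_background,
                                     x$n_windows)) +
    ggplot2::theme_minimal()
}
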