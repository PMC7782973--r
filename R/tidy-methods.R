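## broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a permutation test result
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return A tibble with one row per effect: `effect`, `statistic`,
#'   `df1`, `df2`, `p.value`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(effect = x$effect, statistic = x$statistic,
                 df1 = x$df1, df2 = x$df2, p.value = x$p_value)
}

#' One-row summary of a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return A tibble: `n_effects`, `n_significant` (p < 0.05), `n_perm`,
#'   `seed`.
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(n_effects = nrow(x),
                 n_significant = sum(x$p_value < 0.05),
                 n_perm = x$n_perm[1], seed = x$seed[1])
}

#' Plot a walking-phase profile
#'
#' @param profile Tibble with `phase` and a value column (and optional
#'   grouping columns mapped via `colour`).
#' @param value Name of the value column.
#' @param colour Optional name of a grouping column.
#' @return A ggplot.
#' @export
plot_phase_profile <- function(profile, value, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$phase, y = .data[[value]])
  } else {
    ggplot2::aes(x = .data$phase, y = .data[[value]],
                 colour = .data[[colour]], group = .data[[colour]])
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(x = "walking phase (1 and 9 = low speed / double support)",
                  y = value) +
    ggplot2::theme_minimal()
}

#' Plot per-condition session measures
#'
#' @param conditions Condition table from [run_full()] (`subject`,
#'   `lighting`, `speed`, value column).
#' @param value Name of the value column.
#' @return A ggplot with one panel per lighting level.
#' @export
plot_condition_means <- function(conditions, value = "alpha_power") {
  ggplot2::ggplot(conditions,
                  ggplot2::aes(x = .data$speed, y = .data[[value]])) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          fill = "steelblue", alpha = 0.7) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2) +
    ggplot2::facet_wrap(~lighting) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Scalp topography bar chart of a per-sensor alpha map
#'
#' @param object An `alpha_topography` tibble from
#'   [backproject_alpha_topography()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.alpha_topography <- function(object, ...) {
  topo <- object
  topo$channel <- factor(topo$channel, levels = topo$channel)
  ggplot2::ggplot(topo, ggplot2::aes(x = .data$channel,
                                     y = .data$alpha_power)) +
    ggplot2::geom_col(fill = "darkorange", alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "alpha power (8-12 Hz)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Null-distribution plot of a permutation test
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot of observed statistics per effect with p-values.
#' @export
autoplot.perm_test <- function(object, ...) {
  td <- tidy(object)
  td$label <- sprintf("p = %.4g", td$p.value)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$effect, y = .data$statistic)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "observed statistic") +
    ggplot2::theme_minimal()
}
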