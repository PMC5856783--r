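# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a network ANOVA fit
#'
#' @param x A `network_anova` object.
#' @param ... Unused.
#' @return Per-group tibble with the within-group variability and the pooled
#'   average distance around each group mean.
#' @export
tidy.network_anova <- function(x, ...) x$group_summary

#' Glance at a network ANOVA fit
#'
#' @inheritParams tidy.network_anova
#' @return One-row tibble with the statistic, calibration constant, p-value
#'   and decision.
#' @export
glance.network_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, a = x$a, S = x$S,
                 p_value = x$p_value, alpha = x$alpha, reject = x$reject,
                 m = x$m, n_total = x$n_total, n_nodes = x$n_nodes,
                 calibration = x$calibration$method)
}

#' Tidy a subnetwork path
#'
#' @param x A `subnetwork_path` object.
#' @param ... Unused.
#' @return The per-size tibble of minima, with a `selected` marker.
#' @export
tidy.subnetwork_path <- function(x, ...) {
  out <- x$path
  out$selected <- !is.na(x$j_selected) & out$j == x$j_selected
  out
}

#' @export
glance.subnetwork_path <- function(x, ...) {
  tibble::tibble(j_selected = x$j_selected,
                 statistic = if (is.na(x$j_selected)) NA_real_ else
                   x$path$statistic[match(x$j_selected, x$path$j)],
                 g = x$g, n_nodes = x$n_nodes)
}

#' Tidy a links test
#'
#' @param x A `link_test` object.
#' @param ... Unused.
#' @return The per-link tibble of p-values and significance calls.
#' @export
tidy.link_test <- function(x, ...) x$table

#' @export
glance.link_test <- function(x, ...) {
  tibble::tibble(n_tests = x$n_tests,
                 n_significant = sum(x$table$significant),
                 alpha = x$alpha, global_reject = x$global_reject)
}

#' Plot the per-size minima of the restricted statistic
#'
#' The T_j-versus-j curve used to read off the change point; the selected
#' size, when one exists, is circled.
#'
#' @param object A `subnetwork_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subnetwork_path <- function(object, ...) {
  tb <- tidy(object)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$j, y = .data$statistic)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "subnetwork size j", y = expression(T[j]),
                  title = "Minimal restricted statistic by subnetwork size") +
    ggplot2::theme_minimal()
  if (any(tb$selected)) {
    p <- p + ggplot2::geom_point(data = tb[tb$selected, ], shape = 1,
                                 size = 5, colour = "blue")
  }
  p
}

#' Plot T across the thresholding grids
#'
#' One panel per criterion (fixed correlation / fixed links), with the
#' conventional T < -3 reference line.
#'
#' @param object A `grid_t` tibble from [t_over_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_t <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$value, y = .data$statistic,
                               colour = .data$branch)) +
    ggplot2::geom_hline(yintercept = -3, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~criterion, scales = "free_x") +
    ggplot2::labs(x = "threshold / number of links", y = "T") +
    ggplot2::theme_minimal()
}

#' Plot the null distribution of the T ensemble
#'
#' Histogram of the simulated null T values with the standard normal density
#' overlaid.
#'
#' @param object A `type1_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.type1_experiment <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey70", colour = "white") +
    ggplot2::stat_function(fun = stats::dnorm, colour = "blue") +
    ggplot2::labs(x = "T", y = "density",
                  title = "Null distribution of T vs N(0, 1)") +
    ggplot2::theme_minimal()
}
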