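# ggplot2 views of the main result types.

#' Plot positive:negative differential-epistasis ratios per condition
#'
#' Bar chart of the ratio of positive to negative passing differential
#' epistases in each condition; the dashed line marks parity.
#'
#' @param signs a [sign_summary()] tibble (one row per condition).
#' @return A ggplot object.
#' @export
plot_sign_ratios <- function(signs) {
  ggplot2::ggplot(signs,
                  ggplot2::aes(x = stats::reorder(.data$condition, -.data$ratio),
                               y = .data$ratio)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "condition", y = "positive : negative ratio") +
    ggplot2::theme_minimal()
}

#' Plot the stability distribution of epistatic interactions
#'
#' Histogram of the number of conditions each ever-passing interaction
#' exists in — the U-shape signature: mass at 1 (dynamic) and at the total
#' condition count (stable).
#'
#' @param stability an [epistasis_stability()] table.
#' @return A ggplot object.
#' @export
plot_stability <- function(stability) {
  K <- attr(stability, "n_conditions_total")
  df <- stability |>
    dplyr::filter(.data$n_conditions > 0L) |>
    dplyr::count(.data$n_conditions) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_conditions, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#756bb1") +
    ggplot2::scale_x_continuous(breaks = seq_len(K), limits = c(0.5, K + 0.5)) +
    ggplot2::labs(x = "number of conditions with the interaction",
                  y = "fraction of interactions") +
    ggplot2::theme_minimal()
}

#' Plot a degree distribution on log-log axes
#'
#' @param graph an `igraph` graph (or a [degree_distribution_table()]
#'   tibble).
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(graph) {
  df <- if (inherits(graph, "igraph")) degree_distribution_table(graph) else graph
  df <- df |> dplyr::filter(.data$degree > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "frequency") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot rate_resample_test
autoplot.rate_resample_test <- function(object, ...) {
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = "null mean |rate difference|",
      y = "count",
      title = sprintf("observed = %.4f, p = %.4g", object$observed, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
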