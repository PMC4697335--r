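#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted Gompertz growth curve
#'
#' Observed `ln(OD/OD0)` points with the fitted modified Gompertz curve.
#'
#' @param object A `gompertz_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gompertz_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t = seq(min(object$data$t), max(object$data$t), length.out = 200))
  grid$y <- gompertz_curve(grid$t, object$A, object$mu_max, object$lambda)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(size = 1.8, alpha = 0.8) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(
      x = "time (h)", y = "ln(OD / OD0)",
      title = sprintf("Gompertz fit: mu_max = %.3g / h, lag = %.3g h, Td = %.3g h",
                      object$mu_max, object$lambda, object$generation_time)
    ) +
    ggplot2::theme_minimal()
}

#' Plot butyrate isotopomer class fractions
#'
#' Bar chart of the [2-13C], [4-13C] and [2,4-13C] butyrate fractions, the
#' quantity read off the HMBC correction or predicted by the tracer model.
#'
#' @param fractions Data frame with columns `p2`, `p4`, `p24`; an optional
#'   `experiment_id` column facets the plot.
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(fractions) {
  stopifnot(all(c("p2", "p4", "p24") %in% names(fractions)))
  long <- tidyr::pivot_longer(
    fractions, dplyr::all_of(c("p2", "p4", "p24")),
    names_to = "class", values_to = "fraction")
  long$class <- factor(long$class, levels = c("p4", "p2", "p24"),
                       labels = c("[4-13C]", "[2-13C]", "[2,4-13C]"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "share of labelled butyrate") +
    ggplot2::theme_minimal()
  if ("experiment_id" %in% names(fractions)) {
    p <- p + ggplot2::facet_wrap(~experiment_id)
  }
  p
}

#' Plot a positional isotopomer distribution
#'
#' @param object A `label_propagation` result.
#' @param metabolite Which distribution to show.
#' @param min_prob Patterns below this probability are dropped for
#'   readability.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.label_propagation <- function(object, metabolite = "butyrate",
                                       min_prob = 1e-4, ...) {
  d <- object$distributions[[metabolite]]
  if (is.null(d)) stop("no distribution for '", metabolite, "'",
                       call. = FALSE)
  df <- tibble::tibble(pattern = names(d), prob = unname(d))
  df <- df[df$prob >= min_prob, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pattern,
                                                      -.data$prob),
                                   y = .data$prob)) +
    ggplot2::geom_col(fill = "#b2182b", width = 0.6) +
    ggplot2::labs(x = sprintf("%s 13C pattern (carbon 1 first)", metabolite),
                  y = "probability") +
    ggplot2::theme_minimal()
}
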