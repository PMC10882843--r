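# ggplot2 quick-look methods for the main result types.

#' @export
#' @method autoplot dmm_selection
autoplot.dmm_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$K, y = .data$laplace)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = object$scores[object$scores$K == object$selected_k, ],
      color = "red", size = 3
    ) +
    ggplot2::labs(x = "Number of components K",
                  y = "Laplace negative log evidence",
                  title = "Dirichlet-multinomial mixture model selection") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot enterotype_trajectories
autoplot.enterotype_trajectories <- function(object, ...) {
  ggplot2::ggplot(object$per_pig,
                  ggplot2::aes(x = factor(.data$age_weeks), y = .data$pig_id,
                               fill = factor(.data$enterotype))) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::labs(x = "Age (weeks)", y = "Pig", fill = "Enterotype",
                  title = "Enterotype trajectories") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot trend_fit
autoplot.trend_fit <- function(object, n_grid = 200, level = 0.95, ...) {
  grid <- seq(object$age_range[1], object$age_range[2], length.out = n_grid)
  pred <- predict_trend(object, grid, level = level)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$age, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$age, y = .data$y),
                        inherit.aes = FALSE, alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "Age (weeks)", y = "Outcome",
                  title = sprintf("Penalized-spline trend (phi = %.2f)", object$phi)) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot derivative_band
autoplot.derivative_band <- function(object, ...) {
  wins <- significance_windows(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$derivative)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Age (weeks)", y = "First derivative",
                  title = "Trend derivative with 95% pointwise band") +
    ggplot2::theme_minimal()
  if (nrow(wins)) {
    p <- p + ggplot2::geom_rect(
      data = wins,
      ggplot2::aes(xmin = .data$start_age, xmax = .data$end_age,
                   ymin = -Inf, ymax = Inf, fill = .data$direction),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  p
}

#' Plot maturation scores against age
#'
#' @param scores output of [maturation_scores()].
#' @return a ggplot object.
#' @export
plot_maturation <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$age_weeks, y = .data$score)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pig_id), alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "line", color = "black",
                          linewidth = 1.1) +
    ggplot2::labs(x = "Age (weeks)", y = "Maturation score",
                  title = "Microbiome maturation score by age") +
    ggplot2::theme_minimal()
}
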