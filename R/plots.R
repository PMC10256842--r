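# ggplot2 visualizations for the main result types.

#' Volcano-style plot of a differential abundance table
#'
#' @param diff A [differential_table()] result.
#' @return A ggplot object.
#' @export
plot_differential <- function(diff) {
  ggplot2::ggplot(
    diff,
    ggplot2::aes(
      x = .data$log_fold_change, y = -log10(.data$p_value),
      colour = .data$direction
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$time_point), labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "log2 fold change (treated / control)",
      y = "-log10 one-sided Mann-Whitney p", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Embedding scatter colored by cluster
#'
#' @param embedding An [embed_2d()] result, optionally with a `cluster`
#'   column from [dbscan_cluster()].
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding) {
  colour_var <- if (!is.null(embedding$cluster)) "cluster" else "mechanism"
  ggplot2::ggplot(
    embedding,
    ggplot2::aes(
      x = .data$dim1, y = .data$dim2,
      colour = factor(.data[[colour_var]])
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = colour_var, x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Model benefit vs experimental rescue scatter
#'
#' The benefit-vs-rescue panel: each point is a supplement, x the
#' experimental growth rate under supplementation, y the model-calculated
#' growth benefit for the chosen scenario.
#'
#' @param benefits A [benefit_table()] result (optionally several scenarios).
#' @param experimental Tibble `metabolite`, `growth_rate`.
#' @return A ggplot object.
#' @export
plot_benefit_rescue <- function(benefits, experimental) {
  dat <- dplyr::inner_join(benefits, experimental, by = "metabolite")
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$growth_rate, y = .data$benefit, label = .data$metabolite)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario), scales = "free_y") +
    ggplot2::labs(
      x = "experimental growth rate (1/hr)",
      y = "model growth benefit (1/hr)"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_loocv Confusion-matrix heat map.
#' @param object A `mechanism_loocv` object.
#' @param ... Ignored.
#' @export
autoplot.mechanism_loocv <- function(object, ...) {
  conf <- as_tibble(object$confusion, rownames = "truth") |>
    tidyr::pivot_longer(-"truth", names_to = "predicted", values_to = "fraction")
  ggplot2::ggplot(
    conf,
    ggplot2::aes(x = .data$predicted, y = .data$truth, fill = .data$fraction)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fraction)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_logistic_growth Data and fitted logistic curve.
#' @param object A `growth_fit` object.
#' @param ... Ignored.
#' @export
autoplot.growth_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$od), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(
      x = "time (hr)", y = "OD600",
      title = sprintf("r = %.3g 1/hr, lag = %.3g hr", object$r, object$lag)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_ic50 Percent activity vs concentration with the 4PL fit.
#' @param object An `activity_fit` object.
#' @param ... Ignored.
#' @export
autoplot.activity_fit <- function(object, ...) {
  dat <- object$data
  pos <- dat[dat$concentration > 0, ]
  grid <- tibble(concentration = exp(seq(
    log(min(pos$concentration)), log(max(pos$concentration)),
    length.out = 100
  )))
  grid$activity <- activity_at(object, grid$concentration)
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$concentration, y = .data$activity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "inhibitor concentration", y = "% activity",
      title = sprintf("IC50 = %.4g", object$ic50)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn rank_scenarios Scenario correlations as a ranked bar chart.
#' @param object A `rescue_comparison` object.
#' @param ... Ignored.
#' @export
autoplot.rescue_comparison <- function(object, ...) {
  dat <- as_tibble(object)
  dat$scenario <- stats::reorder(dat$scenario, -dat$rank)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$correlation, y = .data$scenario)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Pearson correlation with experimental rescue",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
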