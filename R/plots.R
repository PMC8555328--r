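#' Plot an LD-decay profile
#'
#' Scatter of pairwise r^2 against map distance with the smoothed curve,
#' the r^2 threshold (dashed) and, when defined, the decay distance
#' (dotted vertical line).
#'
#' @param object An `ld_decay` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ld_decay <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$pairs, ggplot2::aes(x = .data$distance, y = .data$r2)
  ) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "grey40") +
    ggplot2::geom_line(
      data = object$smooth, colour = "steelblue", linewidth = 1
    ) +
    ggplot2::geom_hline(
      yintercept = object$threshold, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Map distance (cM)", y = expression(r^2),
      title = "Intra-chromosomal LD decay"
    ) +
    ggplot2::theme_minimal()
  if (object$crossed) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$decay_distance, linetype = "dotted"
    )
  }
  p
}

#' Plot per-fold cross-validation metrics
#'
#' One point per fold for efficiency and accuracy (both percentages),
#' with the fold mean marked.
#'
#' @param object A `lode_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lode_cv <- function(object, ...) {
  long <- object$per_fold |>
    select("fold", "efficiency", "accuracy") |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(
      fun = mean, geom = "crossbar", width = 0.4, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = NULL, y = "Percent",
      title = sprintf("%d-fold masking cross-validation", object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Mean efficiency and accuracy across folds as functions of the r^2
#' threshold.
#'
#' @param object A `lode_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lode_sweep <- function(object, ...) {
  long <- as_tibble(object) |>
    select("threshold", "mean_efficiency", "mean_accuracy") |>
    tidyr::pivot_longer(
      -"threshold", names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$threshold, y = .data$value, colour = .data$metric
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(r^2 ~ threshold), y = "Percent", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot known versus estimated positions
#'
#' For placements of markers whose true positions are known (e.g. a masked
#' fold), plots estimated against known cM positions of the
#' correctly-assigned markers, one panel per linkage group.
#'
#' @param placements A `lode_placements` tibble.
#' @param truth The genetic map holding the true positions of the placed
#'   markers.
#' @return A ggplot.
#' @export
plot_known_vs_estimated <- function(placements, truth) {
  truth <- validate_map(truth)
  j <- as_tibble(placements) |>
    filter(.data$status == "placed") |>
    left_join(
      truth |> rename(true_lg = "linkage_group", true_pos = "position"),
      by = "marker_id"
    ) |>
    filter(.data$linkage_group == .data$true_lg)
  ggplot2::ggplot(
    j, ggplot2::aes(x = .data$true_pos, y = .data$position)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~linkage_group) +
    ggplot2::labs(
      x = "Known position (cM)", y = "Estimated position (cM)"
    ) +
    ggplot2::theme_minimal()
}
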