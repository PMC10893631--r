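# ggplot2 visualisations for the main result types.

#' Plot a pharmacophore model (xy projection)
#'
#' Feature tolerance spheres and excluded volumes drawn as circles in the
#' xy plane, coloured by feature kind; projected site points are linked
#' to their parents.
#'
#' @param object A `pharmacophore`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pharmacophore <- function(object, ...) {
  f <- object$features
  v <- object$excluded_volumes
  segs <- f |>
    filter(!is.na(.data$parent_id)) |>
    left_join(f[, c("id", "x", "y")], by = c(parent_id = "id"),
              suffix = c("", "_parent"))
  p <- ggplot2::ggplot() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, x = "x (Å)", y = "y (Å)",
                  colour = "kind")
  if (nrow(v)) {
    p <- p + ggplot2::geom_point(
      data = v, ggplot2::aes(.data$x, .data$y, size = .data$radius),
      shape = 21, colour = "grey60", fill = "grey90", alpha = 0.5
    )
  }
  if (nrow(segs)) {
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x_parent, y = .data$y_parent,
                   xend = .data$x, yend = .data$y),
      linetype = "dashed", colour = "grey40"
    )
  }
  p +
    ggplot2::geom_point(
      data = f,
      ggplot2::aes(.data$x, .data$y, colour = .data$kind, size = .data$radius),
      alpha = 0.8
    ) +
    ggplot2::geom_text(
      data = f, ggplot2::aes(.data$x, .data$y, label = .data$id),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_size_continuous(range = c(2, 8), guide = "none")
}

#' Plot the RMSD distribution of a screen
#'
#' Histogram of per-molecule best RMSD, filled by hit verdict, with the
#' hit threshold marked. Unmapped molecules (infinite RMSD) are dropped
#' from the panel.
#'
#' @param object A `screen_report`.
#' @param binwidth Histogram bin width (angstroms).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, binwidth = 0.05, ...) {
  d <- filter(object$results, is.finite(.data$rmsd))
  ggplot2::ggplot(d, ggplot2::aes(.data$rmsd, fill = .data$hit)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$rmsd_threshold,
                        linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("Screen against '%s': %d hits / %d screened",
                      object$query, object$n_hits, object$n_screened),
      x = "best feature RMSD (Å)", y = "molecules", fill = "hit"
    )
}

#' Compare model performance by F1 and Matthews correlation
#'
#' Dot plot of F1 and MCC per model, the package's standard view for
#' choosing among candidate pharmacophore hypotheses; the model with the
#' highest value of `highlight_by` is emphasised.
#'
#' @param rows Metrics tibble with `model`, `f1`, `mcc` columns (e.g.
#'   [benchmark_model_metrics()]).
#' @param highlight_by Metric used to pick the emphasised model.
#' @return A ggplot object.
#' @export
plot_model_performance <- function(rows, highlight_by = "mcc") {
  rows <- as_tibble(rows)
  best <- rows$model[which.max(rows[[highlight_by]])]
  long <- tidyr::pivot_longer(rows[, c("model", "f1", "mcc")],
                              c("f1", "mcc"),
                              names_to = "metric", values_to = "value")
  long$model <- factor(long$model, levels = rows$model)
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$value,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(
      data = filter(long, .data$model == best),
      shape = 1, size = 4, colour = "black"
    ) +
    ggplot2::labs(x = NULL, y = "score", colour = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
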