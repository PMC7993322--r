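#' Plot closed-loop OD trajectories
#'
#' One line per well (true OD), with the setpoint drawn as a horizontal
#' reference line, faceted by plate.
#'
#' @param object A `turbidostat_sim`.
#' @param measure `"od_true"` (default) or `"od_meas"`.
#' @param alpha Line transparency (useful with hundreds of wells).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot turbidostat_sim
#' @export
autoplot.turbidostat_sim <- function(object, measure = c("od_true", "od_meas"),
                                     alpha = 0.3, ...) {
  measure <- match.arg(measure)
  ggplot2::ggplot(object$records,
                  ggplot2::aes(.data$t_hours, .data[[measure]],
                               group = interaction(.data$plate, .data$well))) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::geom_hline(yintercept = object$cfg$x_set,
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$plate)) +
    ggplot2::labs(x = "time (h)", y = "OD600",
                  title = "Turbidostat trajectories") +
    ggplot2::theme_minimal()
}

#' Plot a growth or expression landscape over the nutrient grid
#'
#' Carbon x nitrogen tiles, faceted by phosphorus level, coloured by the
#' chosen summary column.
#'
#' @param summary A landscape table from [summarize_landscape()].
#' @param fill Column to colour by (`"k_mean"` or `"fluor_mean"`).
#' @return A ggplot object.
#' @export
plot_landscape <- function(summary, fill = c("k_mean", "fluor_mean")) {
  fill <- match.arg(fill)
  ggplot2::ggplot(summary,
                  ggplot2::aes(factor(.data$c_mult), factor(.data$n_mult),
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$p_mult), labeller = "label_both") +
    ggplot2::scale_fill_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = "carbon (fold vs 1x M9)", y = "nitrogen (fold vs 1x M9)",
                  fill = fill) +
    ggplot2::theme_minimal()
}

#' Plot the point spread of a tracer across the plate
#'
#' Plate heat maps of tracer concentration, one facet per iteration.
#'
#' @param object A `point_spread` result.
#' @param iterations Which iterations to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot point_spread
#' @export
autoplot.point_spread <- function(object, iterations = NULL, ...) {
  rows <- attr(object, "rows"); cols <- attr(object, "cols")
  d <- as_tibble(object)
  if (!is.null(iterations)) d <- filter(d, .data$iteration %in% iterations)
  idx <- well_to_index(d$well, rows, cols)
  d$row <- (idx - 1L) %/% cols + 1L
  d$col <- (idx - 1L) %% cols + 1L
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$concentration)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(rows),
                             labels = LETTERS[seq_len(rows)]) +
    ggplot2::scale_x_continuous(breaks = seq_len(cols)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$iteration), labeller = "label_both") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tracer") +
    ggplot2::theme_minimal()
}

#' Gantt chart of a deck schedule
#'
#' Busy intervals per physical resource, coloured by plate, showing how
#' reading one plate overlaps pipetting of another.
#'
#' @param object A `deck_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deck_schedule
#' @export
autoplot.deck_schedule <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(xmin = .data$t_start_min, xmax = .data$t_end_min,
                               ymin = as.numeric(factor(.data$resource)) - 0.4,
                               ymax = as.numeric(factor(.data$resource)) + 0.4,
                               fill = .data$plate)) +
    ggplot2::geom_rect(colour = "grey30") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(factor(object$steps$resource))),
      labels = levels(factor(object$steps$resource))) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = "Asynchronous deck schedule") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
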