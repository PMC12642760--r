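# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rendered field-magnitude grid
#'
#' @param object A `field_grid` from [render_grid()].
#' @param trans Transformation for the fill scale (field magnitudes span
#'   decades; default `"log10"` with a floor).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.field_grid <- function(object, trans = "log10", ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$mag <- as.vector(object$z)
  floor_val <- max(min(df$mag[df$mag > 0], na.rm = TRUE), 1e-12)
  df$mag <- pmax(df$mag, floor_val)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "|E|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
}

#' Plot agent trajectories from a trace
#'
#' @param trace An `episode_trace`.
#' @return A ggplot of per-agent paths over the arena.
#' @export
plot_trajectories <- function(trace) {
  ggplot2::ggplot(trace$states,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = factor(.data$agent_id))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal(xlim = c(0, trace$config$width_cm),
                         ylim = c(0, trace$config$height_cm)) +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", color = "agent")
}

#' Plot an SPI tail fit on the log-survival scale
#'
#' @param object An `spi_tail_fit`.
#' @param ... Unused.
#' @return A ggplot: empirical log-survival points, the fitted log-linear
#'   line, and the tail cut.
#' @export
autoplot.spi_tail_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$log_survival), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::geom_vline(xintercept = object$cut_value_s, linetype = 2) +
    ggplot2::labs(x = "SPI (s)", y = "log survival")
}

#' Plot a social EOD motif table
#'
#' @param object A `motif_table` from [mine_social_motifs()].
#' @param ... Unused.
#' @return A ggplot bar chart of the top motifs (pair patterns as labels).
#' @export
autoplot.motif_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste(df$motif_a, df$motif_b, sep = "\n")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      -.data$count),
                                   y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "motif (agent pair EOD patterns)", y = "occurrences")
}

#' Plot training telemetry
#'
#' @param object An `efish_training` result.
#' @param ... Unused.
#' @return A ggplot of mean food per episode and mean EOD rate over
#'   training.
#' @export
autoplot.efish_training <- function(object, ...) {
  df <- object$log |>
    dplyr::select(.data$env_steps, .data$mean_food, .data$mean_eod_rate) |>
    tidyr::pivot_longer(-.data$env_steps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$env_steps, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "environment steps", y = NULL)
}
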