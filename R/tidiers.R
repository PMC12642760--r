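# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SPI tail fit
#'
#' @param x An `spi_tail_fit`.
#' @param ... Unused.
#' @return Tibble with one row per survival point: `interval_s`,
#'   `log_survival`, `fitted`, `in_fit_region`.
#' @export
tidy.spi_tail_fit <- function(x, ...) {
  tibble::tibble(interval_s = x$bin_centers_s,
                 log_survival = x$log_survival,
                 fitted = x$intercept + x$slope * x$bin_centers_s,
                 in_fit_region = x$bin_centers_s <= x$cut_value_s)
}

#' @rdname tidy.spi_tail_fit
#' @return `glance()` returns a one-row tibble: `slope`, `intercept`,
#'   `excess_mass`, `cut_value_s`, `n_intervals`.
#' @export
glance.spi_tail_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 excess_mass = x$excess_mass, cut_value_s = x$cut_value_s,
                 n_intervals = x$n_intervals)
}

#' Tidy a training run
#'
#' @param x An `efish_training` result.
#' @param ... Unused.
#' @return `tidy()`: the per-iteration telemetry log; `glance()`: a one-row
#'   summary of the final iteration.
#' @export
tidy.efish_training <- function(x, ...) x$log

#' @rdname tidy.efish_training
#' @export
glance.efish_training <- function(x, ...) {
  if (!nrow(x$log)) return(tibble::tibble())
  last <- x$log[nrow(x$log), ]
  tibble::tibble(iterations = nrow(x$log), env_steps = last$env_steps,
                 final_mean_food = last$mean_food,
                 final_mean_eod_rate = last$mean_eod_rate,
                 final_entropy = last$entropy)
}

#' Tidy a two-fish assay
#'
#' @param x A `two_fish_assay` result.
#' @param ... Unused.
#' @return `tidy()`: one row per run; `glance()`: the per-condition
#'   summary.
#' @export
tidy.two_fish_assay <- function(x, ...) x$runs

#' @rdname tidy.two_fish_assay
#' @export
glance.two_fish_assay <- function(x, ...) x$summary
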