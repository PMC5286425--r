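#' Generations since isolation from an inbreeding gain
#'
#' Inverts the stationary drift recursion `dF = 1 - (1 - 1/(2 Ne))^t` for
#' `t` given the observed inbreeding coefficient, its assumed value at the
#' population split, and an effective size: `t = log(1 - dF) /
#' log(1 - 1/(2 Ne))`, real-valued.
#'
#' @param f_obs Observed inbreeding coefficient, in `(f0, 1)`.
#' @param f0 Initial inbreeding coefficient at the split, `0 <= f0 < f_obs`.
#' @param ne Effective size (>= 1).
#' @return Generations since isolation (not rounded).
#' @export
#' @examples
#' time_since_isolation(0.22166, 0, 100)
time_since_isolation <- function(f_obs, f0, ne) {
  stopifnot(all(ne >= 1))
  if (any(f0 < 0) || any(f_obs >= 1)) {
    stop_isopop("need 0 <= f0 < f_obs < 1")
  }
  if (any(f0 >= f_obs)) stop_isopop("no inbreeding gain: f0 >= f_obs")
  dF <- f_obs - f0
  log(1 - dF) / log(1 - 1 / (2 * ne))
}

#' Effective size compatible with an inbreeding gain over a given time
#'
#' The same recursion solved for `Ne`:
#' `Ne = 1 / (2 (1 - (1 - dF)^(1/t)))`.
#'
#' @param f_obs,f0 As in [time_since_isolation()].
#' @param t Generations since isolation (> 0).
#' @return Effective population size.
#' @export
ne_given_time <- function(f_obs, f0, t) {
  stopifnot(all(t > 0))
  if (any(f0 < 0) || any(f_obs >= 1)) {
    stop_isopop("need 0 <= f0 < f_obs < 1")
  }
  if (any(f0 >= f_obs)) stop_isopop("no inbreeding gain: f0 >= f_obs")
  dF <- f_obs - f0
  1 / (2 * (1 - (1 - dF)^(1 / t)))
}

#' (Ne, t) envelope compatible with an observed inbreeding coefficient
#'
#' For a population with inbreeding coefficient `f_obs`, the initial
#' inbreeding at the split is assumed to lie between the lowest and highest
#' values observed among open populations; at every candidate time since
#' isolation the corresponding effective-size boundaries follow from
#' [ne_given_time()]. Open values at or above `f_obs` are excluded with a
#' warning.
#'
#' @param f_obs Observed inbreeding coefficient.
#' @param open_f_values Inbreeding coefficients of the open populations.
#' @param t_grid Generations at which to evaluate the envelope.
#' @param population Optional label.
#' @param years_per_generation Conversion used by the `years` column
#'   (default 29).
#' @return A `timing_envelope` tibble: `t`, `years`, `ne_low`, `ne_high`,
#'   with attributes `f_obs`, `f0_low`, `f0_high`.
#' @export
isolation_envelope <- function(f_obs, open_f_values, t_grid,
                               population = NA_character_,
                               years_per_generation = 29) {
  usable <- open_f_values[open_f_values < f_obs]
  if (length(usable) == 0) {
    stop_isopop("every open-population F is at or above f_obs")
  }
  if (length(usable) < length(open_f_values)) {
    warn(sprintf("excluded %d open F value(s) >= f_obs",
                 length(open_f_values) - length(usable)))
  }
  f0_low <- min(usable); f0_high <- max(usable)
  out <- tibble(
    population = population, t = as.numeric(t_grid),
    years = as.numeric(t_grid) * years_per_generation,
    ne_low = ne_given_time(f_obs, f0_low, as.numeric(t_grid)),
    ne_high = ne_given_time(f_obs, f0_high, as.numeric(t_grid)))
  attr(out, "f_obs") <- f_obs
  attr(out, "f0_low") <- f0_low
  attr(out, "f0_high") <- f0_high
  class(out) <- c("timing_envelope", class(out))
  out
}

#' @rdname isolation_envelope
#' @param object A `timing_envelope`.
#' @param ... Unused.
#' @export
autoplot.timing_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ne_low,
                                      ymax = .data$ne_high),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ne_low), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ne_high), colour = "steelblue4") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations since isolation",
                  y = "compatible effective size Ne") +
    ggplot2::theme_minimal()
}
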