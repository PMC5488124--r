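# Plotting and broom-style summaries for simulation results and compiled
# models.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a simulated time series
#'
#' Concentration-time curves for the selected variables (all non-time
#' columns by default), one colored line per variable.
#'
#' @param object An `mpc_timeseries` from [integrate_odes()] or
#'   [lagged_normal_input()].
#' @param vars Optional character vector of variable columns to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpc_timeseries
#' @export
autoplot.mpc_timeseries <- function(object, vars = NULL, ...) {
  vars <- vars %||% setdiff(names(object), "t")
  long <- tidyr::pivot_longer(dplyr::select(object, "t", dplyr::all_of(vars)),
                              -"t", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (mM)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.mpc_timeseries <- function(x, ...) print(autoplot(x, ...))

#' Tidy a compiled model's parameter table
#'
#' @param x An `mpc_model`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `name`, `printed_value` (as
#'   written in the model file), `value` (after the per-minute time-unit
#'   conversion), and `unit`.
#' @method tidy mpc_model
#' @export
tidy.mpc_model <- function(x, ...) {
  dplyr::select(x$params, "name", "printed_value", "value", "unit")
}

#' One-row summary of a compiled model
#'
#' @param x An `mpc_model`.
#' @param ... Unused.
#' @return A one-row tibble: model name, state/parameter/algebraic/extern
#'   counts, and the time grid.
#' @method glance mpc_model
#' @export
glance.mpc_model <- function(x, ...) {
  tibble::tibble(name = x$name, n_states = nrow(x$states),
                 n_params = nrow(x$params),
                 n_algebraics = length(x$algebraics),
                 n_externs = nrow(x$externs),
                 t_min = x$grid$t_min, t_max = x$grid$t_max,
                 delta = x$grid$delta)
}

#' @importFrom rlang .data %||%
NULL
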