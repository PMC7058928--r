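# Broom-style accessors and ggplot2 autoplot methods.

#' Tidy a circuit fit
#'
#' @param x A `"circuit_fit"` from [fit_hill()], [fit_interference()] or
#'   [fit_timescales()].
#' @param ... Unused.
#' @return One row per estimated parameter: `term`, `estimate`,
#'   `at_constraint`.
#' @method tidy circuit_fit
#' @export
tidy.circuit_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    at_constraint = unname(x$constraint_active[names(x$estimates)])
  )
}

#' Glance at a circuit fit
#'
#' @inheritParams tidy.circuit_fit
#' @return A one-row tibble: `fit_type`, `residual_norm`, `converged`, `n_obs`.
#' @method glance circuit_fit
#' @export
glance.circuit_fit <- function(x, ...) {
  tibble::tibble(fit_type = x$type, residual_norm = x$residual_norm,
                 converged = x$converged, n_obs = x$n_obs)
}

#' Tidy a predicted state table
#'
#' @param x A `"state_table"` from [truth_table_prediction()].
#' @param ... Unused.
#' @return The table without the per-node list-column.
#' @method tidy state_table
#' @export
tidy.state_table <- function(x, ...) {
  tibble::as_tibble(x[, c("state", "bits", "output", "target")])
}

#' Plot a predicted state table
#'
#' Bar plot of predicted output flux per input state, colored by the
#' required logic level where one is attached.
#'
#' @param object A `"state_table"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot state_table
#' @export
autoplot.state_table <- function(object, ...) {
  df <- tidy.state_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bits, y = .data$output,
                                   fill = .data$target)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(
      values = c(`1` = "#2166ac", `0` = "#b2182b", X = "grey60"),
      labels = c(`1` = "required ON", `0` = "required OFF", X = "don't care"),
      name = NULL) +
    ggplot2::labs(x = "input state (MSB first)", y = "predicted output (RPU)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a simulated trajectory
#'
#' Line plot of per-node flux over time, faceted by node class, with the
#' instantaneous steady-state targets dashed.
#'
#' @param object A `"circuit_trajectory"` from [simulate_circuit()].
#' @param nodes Optional subset of node ids to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circuit_trajectory
#' @export
autoplot.circuit_trajectory <- function(object, nodes = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(nodes)) df <- df[df$node %in% nodes, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$flux,
                                   color = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$flux_ss), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "flux (RPU)") +
    ggplot2::theme_minimal()
}

#' Plot a power time course
#'
#' @param object A `"power_timecourse"` from [trajectory_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_timecourse
#' @export
autoplot.power_timecourse <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$total)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "time (h)",
                  y = expression(J[RNAP] ~ "(total promoter flux, RPU)")) +
    ggplot2::theme_minimal()
}
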