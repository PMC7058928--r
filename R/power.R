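# RNAP-flux power accounting.
#
# The power metric J_RNAP sums the RNAP flux over every promoter instance
# physically present in the construct: each tandem input promoter of every
# gate separately (the upstream instance interference-corrected by its
# downstream partner's occupancy), plus the reporter-driving output
# promoter(s). Constitutive promoters on the sensor plasmids (regulator
# expression) are not part of the circuit construct and are excluded.

# One row per physical promoter instance, given per-node output fluxes and
# occupancy factors (named vectors over netlist nodes).
power_breakdown <- function(netlist, out, occ) {
  rows <- list()
  for (i in seq_len(nrow(netlist))) {
    r <- netlist[i, ]
    if (r$type == "INPUT") next
    if (r$type == "NOT" || (r$type == "OUTPUT" && is.na(r$in2))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        site = r$node, position = 1L, promoter_node = r$in1,
        flux = out[[r$in1]])
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        site = rep(r$node, 2), position = c(1L, 2L),
        promoter_node = c(r$in1, r$in2),
        flux = c(occ[[r$in2]] * out[[r$in1]], out[[r$in2]]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Total RNAP flux of one circuit state
#'
#' Sums the RNAP flux over all promoter instances of the construct for one
#' evaluated circuit state — a proxy for the circuit's "power" draw on the
#' host's polymerase pool. Each gate's output promoter is counted once per
#' physical placement (so a promoter feeding two gates contributes two
#' instances), with interference-corrected flux for upstream tandem
#' positions.
#'
#' @param node_states Per-node state tibble from [evaluate_state()].
#' @param netlist The `"circuit_netlist"` the states were evaluated on.
#' @return A `"power_report"` tibble with one row per promoter instance
#'   (`site`, `position`, `promoter_node`, `flux`); the total is the sum of
#'   the `flux` column, also stored in `attr(, "total")`.
#' @export
#' @examples
#' lib <- builtin_library()
#' nl <- circuit_netlist(tibble::tibble(
#'   node = c("x1", "g1", "out"), type = c("INPUT", "NOT", "OUTPUT"),
#'   in1 = c(NA, "x1", "g1"), sensor = c("P_Tac", NA, NA)))
#' asg <- new_assignment(c(g1 = "P1-PhlF"))
#' st <- evaluate_state(nl, asg, lib, 1)
#' sum(state_power(st, nl)$flux)
state_power <- function(node_states, netlist) {
  missing <- setdiff(netlist$node, node_states$node)
  if (length(missing))
    abort(paste0("Evaluation error: no node state for: ",
                 paste(missing, collapse = ", ")))
  out <- stats::setNames(node_states$output_flux, node_states$node)
  occ <- stats::setNames(node_states$occupancy_factor, node_states$node)
  bd <- power_breakdown(netlist, out, occ)
  class(bd) <- c("power_report", class(tibble::tibble()))
  attr(bd, "total") <- sum(bd$flux)
  bd
}

#' Total RNAP flux along a trajectory
#'
#' Evaluates [state_power()] at every time point of a simulated trajectory,
#' using the instantaneous node fluxes and occupancy factors recorded by
#' [simulate_circuit()].
#'
#' @param trajectory A `"circuit_trajectory"`.
#' @param netlist Netlist the trajectory was simulated on; defaults to the
#'   one stored on the trajectory.
#' @return A tibble with one row per trajectory time point: `time`, `total`
#'   (RPU), and the per-promoter `breakdown` as a list-column.
#' @export
trajectory_power <- function(trajectory, netlist = NULL) {
  netlist <- netlist %||% attr(trajectory, "netlist")
  if (is.null(netlist))
    abort("`netlist` is required when the trajectory does not carry one.")
  circ <- trajectory[trajectory$type != "reporter", ]
  times <- unique(circ$time)
  res <- purrr::map_dfr(times, function(tt) {
    slice <- circ[circ$time == tt, ]
    out <- stats::setNames(slice$flux, slice$node)
    occ <- stats::setNames(slice$occupancy, slice$node)
    bd <- power_breakdown(netlist, out, occ)
    tibble::tibble(time = tt, total = sum(bd$flux), breakdown = list(bd))
  })
  class(res) <- c("power_timecourse", class(tibble::tibble()))
  res
}
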