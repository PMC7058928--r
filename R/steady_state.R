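#' Hill repression response of a gate
#'
#' The steady-state NOT-gate response maps total input promoter flux `x`
#' (RPU) to output promoter flux (RPU):
#' `y = y_min + (y_max - y_min) * K^n / (K^n + x^n)`.
#' The response is strictly decreasing in `x`, equals `y_max` at `x = 0` and
#' approaches `y_min` as `x` grows.
#'
#' @param gate A gate record (one row of `gate_library()$gates`).
#' @param x Input flux in RPU; vectorized, must be non-negative.
#' @return Output flux in RPU, same length as `x`.
#' @export
#' @examples
#' lib <- builtin_library()
#' phlf <- dplyr::filter(lib$gates, name == "P1-PhlF")
#' hill_response(phlf, 0)      # y_max = 6.9
#' hill_response(phlf, 0.04)   # half repression: (y_max + y_min) / 2
hill_response <- function(gate, x) {
  if (any(x < 0)) abort("Input flux `x` must be non-negative.")
  Kn <- gate$K^gate$n
  gate$y_min + (gate$y_max - gate$y_min) * Kn / (Kn + x^gate$n)
}

#' Tandem-promoter interference factor
#'
#' When two promoters sit in series, repressor bound at the downstream
#' promoter can roadblock RNAP elongating from the upstream promoter, and
#' the downstream promoter region additionally suppresses the upstream one
#' non-specifically. The upstream flux is multiplied by the occupancy factor
#'
#' `f = alpha * (K^n + beta * x_down^n) / (K^n + x_down^n)`
#'
#' where `alpha`, `beta`, `K`, `n` belong to the *downstream* node's gate and
#' `x_down` is that node's own total input flux (which sets its repressor
#' level, hence occupancy of its output promoter). The factor decreases from
#' `alpha` (repressor unbound) to `alpha * beta` (fully bound); with
#' `alpha = beta = 1` interference vanishes and composition is additive.
#'
#' Sensor output promoters use a two-state rule, since only their OFF/ON
#' endpoint occupancies are characterized: a repressor-based sensor
#' contributes `alpha` when ON (repressor cleared by the inducer) and
#' `alpha * beta` when OFF (repressor bound); an activator-based sensor
#' always contributes `alpha`.
#'
#' @param record A gate record, or a sensor record (identified by its
#'   `off_rpu` column).
#' @param x_down For a gate: the downstream node's total input flux (RPU,
#'   vectorized, non-negative). For a sensor: its logical state (`TRUE` = ON).
#' @return Dimensionless factor in `[alpha * beta, alpha]`.
#' @export
roadblock_factor <- function(record, x_down) {
  if ("off_rpu" %in% names(record)) {           # sensor: two-state rule
    on <- as.logical(x_down)
    if (record$mode == "activator") {
      rep(record$alpha, length(on))
    } else {
      ifelse(on, record$alpha, record$alpha * record$beta)
    }
  } else {
    if (any(x_down < 0)) abort("`x_down` must be non-negative.")
    Kn <- record$K^record$n
    xn <- x_down^record$n
    record$alpha * (Kn + record$beta * xn) / (Kn + xn)
  }
}

#' Compose two tandem promoter fluxes
#'
#' Total flux delivered by a tandem promoter pair: the upstream promoter's
#' raw flux attenuated by the downstream occupancy factor, plus the
#' downstream promoter's flux. With `factor = 1` this reduces exactly to the
#' additive model `x = x1 + x2`.
#'
#' @param y_upstream_raw Upstream promoter flux (RPU) before interference.
#' @param factor Interference factor from [roadblock_factor()], in (0, 1].
#' @param y_downstream Downstream promoter flux (RPU).
#' @return Combined flux in RPU.
#' @export
compose_tandem <- function(y_upstream_raw, factor, y_downstream) {
  factor * y_upstream_raw + y_downstream
}

# Core evaluator, vectorized over a set of input states.
#
# Returns a list with per-node numeric matrices/vectors over `states`
# (integers 0 .. 2^n - 1, input 1 = least-significant bit):
#   $x, $out, $occ  — named lists of length-|states| vectors per node
#   $output         — circuit output flux per state
evaluate_states_core <- function(netlist, assignment, library, states,
                                 model = c("interference", "additive")) {
  model <- match.arg(model)
  inputs <- netlist_inputs(netlist)
  node_to_gate <- assignment$node_to_gate
  x <- list(); out <- list(); occ <- list()
  S <- length(states)
  output <- NULL

  for (i in seq_len(nrow(netlist))) {
    r <- netlist[i, ]
    if (r$type == "INPUT") {
      sens <- lib_sensor(library, r$sensor)
      bit <- bitwAnd(bitwShiftR(states, match(r$node, inputs) - 1L), 1L) == 1L
      x[[r$node]] <- rep(NA_real_, S)
      out[[r$node]] <- ifelse(bit, sens$on_rpu, sens$off_rpu)
      occ[[r$node]] <- if (model == "additive") rep(1, S) else
        roadblock_factor(sens, bit)
    } else if (r$type %in% c("NOT", "NOR2")) {
      gname <- node_to_gate[[r$node]]
      if (is.null(gname) || is.na(gname))
        abort(paste0("Assignment error: node '", r$node, "' has no gate."))
      gate <- lib_gate(library, gname)
      xi <- if (r$type == "NOT") {
        out[[r$in1]]
      } else {
        compose_tandem(out[[r$in1]], occ[[r$in2]], out[[r$in2]])
      }
      x[[r$node]] <- xi
      out[[r$node]] <- hill_response(gate, xi)
      occ[[r$node]] <- if (model == "additive") rep(1, S) else
        roadblock_factor(gate, xi)
    } else {                                     # OUTPUT
      flux <- if (is.na(r$in2)) out[[r$in1]] else
        compose_tandem(out[[r$in1]], occ[[r$in2]], out[[r$in2]])
      x[[r$node]] <- flux
      out[[r$node]] <- flux
      occ[[r$node]] <- rep(1, S)
      output <- flux
    }
  }
  list(x = x, out = out, occ = occ, output = output)
}

check_assignment_total <- function(netlist, assignment) {
  gate_nodes <- netlist$node[netlist$type %in% c("NOT", "NOR2")]
  missing <- setdiff(gate_nodes, names(assignment$node_to_gate))
  if (length(missing))
    abort(paste0("Assignment error: unassigned node(s): ",
                 paste(missing, collapse = ", ")))
}

#' Steady-state evaluation of one circuit state
#'
#' Evaluates the circuit in topological order for a single combination of
#' sensor states. `INPUT` nodes emit their sensor's OFF/ON flux; each gate
#' node's total input is the (interference-corrected) tandem composition of
#' its parents' output promoter fluxes; its output is the Hill response to
#' that input.
#'
#' @param netlist A `"circuit_netlist"`.
#' @param assignment A `"gate_assignment"` (see [new_assignment()]), total
#'   over the gate nodes.
#' @param library A `"gate_library"`.
#' @param input_bits Logical/0-1 vector, one entry per `INPUT` node in
#'   netlist row order (input 1 first).
#' @param model `"interference"` (default) or `"additive"` (all occupancy
#'   factors forced to 1).
#' @return A tibble with one row per node: `node`, `type`, `gate`,
#'   `total_input`, `output_flux`, `occupancy_factor`.
#' @export
evaluate_state <- function(netlist, assignment, library, input_bits,
                           model = c("interference", "additive")) {
  model <- match.arg(model)
  check_assignment_total(netlist, assignment)
  inputs <- netlist_inputs(netlist)
  input_bits <- as.integer(as.logical(input_bits))
  if (length(input_bits) != length(inputs))
    abort(paste0("`input_bits` must have one entry per INPUT node (",
                 length(inputs), ")."))
  state <- sum(input_bits * 2L^(seq_along(input_bits) - 1L))
  res <- evaluate_states_core(netlist, assignment, library, state, model)
  tibble::tibble(
    node = netlist$node,
    type = netlist$type,
    gate = dplyr::coalesce(
      unname(assignment$node_to_gate[netlist$node]),
      netlist$sensor
    ),
    total_input = unname(vapply(netlist$node, function(n) res$x[[n]][1], numeric(1))),
    output_flux = unname(vapply(netlist$node, function(n) res$out[[n]][1], numeric(1))),
    occupancy_factor = unname(vapply(netlist$node, function(n) res$occ[[n]][1], numeric(1)))
  )
}

state_bits_chr <- function(states, n) {
  vapply(states, function(s)
    paste(rev(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L)), collapse = ""),
    character(1))
}

#' Predict the full state table of a circuit
#'
#' Evaluates every input bit-vector (all `2^n` rows in canonical binary
#' order; input 1 is the least-significant bit, so state 4 = `0100` means
#' only input 3 is on) and tabulates the predicted output flux. If a
#' `"truth_spec"` is supplied, its required logic level is attached as the
#' `target` column (`"1"`, `"0"` or `"X"` for don't-care).
#'
#' @inheritParams evaluate_state
#' @param spec Optional `"truth_spec"` giving required output levels.
#' @return A `"state_table"` tibble with columns `state`, `bits`, `output`
#'   (RPU) and `target`; per-node states are in the `nodes` list-column.
#' @export
truth_table_prediction <- function(netlist, assignment, library,
                                   model = c("interference", "additive"),
                                   spec = NULL) {
  model <- match.arg(model)
  check_assignment_total(netlist, assignment)
  n <- length(netlist_inputs(netlist))
  states <- 0:(2^n - 1)
  res <- evaluate_states_core(netlist, assignment, library, states, model)
  target <- if (is.null(spec)) rep("X", length(states)) else {
    if (!identical(nrow(spec), length(states)))
      abort("`spec` row count does not match the netlist's input count.")
    spec$output
  }
  nodes <- lapply(seq_along(states), function(k) {
    tibble::tibble(
      node = netlist$node, type = netlist$type,
      total_input = unname(vapply(netlist$node, function(nm) res$x[[nm]][k], numeric(1))),
      output_flux = unname(vapply(netlist$node, function(nm) res$out[[nm]][k], numeric(1))),
      occupancy_factor = unname(vapply(netlist$node, function(nm) res$occ[[nm]][k], numeric(1)))
    )
  })
  out <- tibble::tibble(
    state = states,
    bits = state_bits_chr(states, n),
    output = res$output,
    target = target,
    nodes = nodes
  )
  class(out) <- c("state_table", class(tibble::tibble()))
  attr(out, "model") <- model
  out
}

#' Separation score of a predicted state table
#'
#' The score is the ratio of the lowest predicted flux over states required
#' ON to the highest predicted flux over states required OFF; don't-care
#' rows are excluded. A score above 1 means the ON and OFF populations are
#' separated; larger is better.
#'
#' @param table A `"state_table"` from [truth_table_prediction()] whose
#'   `target` column contains at least one `"1"` and one `"0"`.
#' @return A single dimensionless score.
#' @export
circuit_score <- function(table) {
  on <- table$output[table$target == "1"]
  off <- table$output[table$target == "0"]
  if (length(on) == 0 || length(off) == 0)
    abort("Score requires at least one required-ON and one required-OFF row.")
  min(on) / max(off)
}

#' Tandem-promoter validation suite
#'
#' Builds the two-NOT test circuits used to probe tandem-promoter
#' interference: each circuit wires one sensor (`P_Tac`) through an upstream
#' NOT gate and a second sensor (`P_Tet`) through a downstream NOT gate,
#' with the two gate output promoters in tandem driving the reporter
#' (a NAND function overall). Every circuit is predicted in all four
#' inducer combinations.
#'
#' Gate pairs are chosen deterministically: the first `n_circuits` ordered
#' pairs of library gates with distinct repressor families, in library
#' order.
#'
#' @param library A `"gate_library"` containing sensors `P_Tac` and `P_Tet`.
#' @param n_circuits Number of two-NOT circuits to build (default 20).
#' @param model Composition model passed to [truth_table_prediction()].
#' @return A tibble with `n_circuits * 4` rows: `circuit`, `upstream_gate`,
#'   `downstream_gate`, `state`, `bits`, `output` (RPU).
#' @export
tandem_validation_suite <- function(library, n_circuits = 20,
                                    model = c("interference", "additive")) {
  model <- match.arg(model)
  g <- library$gates
  pairs <- expand.grid(up = seq_len(nrow(g)), down = seq_len(nrow(g)))
  pairs <- pairs[g$family[pairs$up] != g$family[pairs$down], ]
  pairs <- pairs[order(pairs$up, pairs$down), ]
  if (nrow(pairs) < n_circuits)
    abort("Library too small for the requested number of tandem circuits.")
  pairs <- pairs[seq_len(n_circuits), ]

  nl <- circuit_netlist(tibble::tibble(
    node = c("x1", "x2", "g_up", "g_down", "out"),
    type = c("INPUT", "INPUT", "NOT", "NOT", "OUTPUT"),
    in1  = c(NA, NA, "x1", "x2", "g_up"),
    in2  = c(NA, NA, NA, NA, "g_down"),
    sensor = c("P_Tac", "P_Tet", NA, NA, NA)
  ))
  purrr::pmap_dfr(pairs, function(up, down) {
    asg <- new_assignment(c(g_up = g$name[up], g_down = g$name[down]))
    tab <- truth_table_prediction(nl, asg, library, model = model)
    tibble::tibble(
      circuit = paste0(g$name[up], "~", g$name[down]),
      upstream_gate = g$name[up],
      downstream_gate = g$name[down],
      state = tab$state, bits = tab$bits, output = tab$output
    )
  })
}
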