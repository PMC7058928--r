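# Shared fixtures and independent oracles for the test suite.
# The oracles deliberately re-derive everything from first principles
# (recursion and exhaustive enumeration) without touching the package's
# evaluators, so agreement is informative.

# ---- independent recursive steady-state evaluator ---------------------------
# Evaluates one node's output flux by plain recursion over the wiring
# diagram, recomputing the Hill response and occupancy factor inline.
oracle_eval_node <- function(netlist, assignment, library, bits, node,
                             model = "interference") {
  row <- netlist[netlist$node == node, ]
  hill <- function(g, x) g$y_min + (g$y_max - g$y_min) * g$K^g$n / (g$K^g$n + x^g$n)
  occ_of <- function(nd) {
    r <- netlist[netlist$node == nd, ]
    if (model == "additive") return(1)
    if (r$type == "INPUT") {
      s <- library$sensors[library$sensors$name == r$sensor, ]
      i <- match(nd, netlist$node[netlist$type == "INPUT"])
      if (s$mode == "activator") s$alpha
      else if (bits[i]) s$alpha else s$alpha * s$beta
    } else {
      g <- library$gates[library$gates$name == assignment$node_to_gate[[nd]], ]
      x <- oracle_input_of(netlist, assignment, library, bits, nd, model)
      g$alpha * (g$K^g$n + g$beta * x^g$n) / (g$K^g$n + x^g$n)
    }
  }
  if (row$type == "INPUT") {
    s <- library$sensors[library$sensors$name == row$sensor, ]
    i <- match(node, netlist$node[netlist$type == "INPUT"])
    return(if (bits[i]) s$on_rpu else s$off_rpu)
  }
  if (row$type == "OUTPUT") {
    up <- oracle_eval_node(netlist, assignment, library, bits, row$in1, model)
    if (is.na(row$in2)) return(up)
    down <- oracle_eval_node(netlist, assignment, library, bits, row$in2, model)
    return(occ_of(row$in2) * up + down)
  }
  g <- library$gates[library$gates$name == assignment$node_to_gate[[node]], ]
  x <- oracle_input_of(netlist, assignment, library, bits, node, model)
  hill(g, x)
}

oracle_input_of <- function(netlist, assignment, library, bits, node, model) {
  row <- netlist[netlist$node == node, ]
  up <- oracle_eval_node(netlist, assignment, library, bits, row$in1, model)
  if (row$type == "NOT") return(up)
  down <- oracle_eval_node(netlist, assignment, library, bits, row$in2, model)
  occ2 <- if (model == "additive") 1 else {
    r2 <- netlist[netlist$node == row$in2, ]
    if (r2$type == "INPUT") {
      s <- library$sensors[library$sensors$name == r2$sensor, ]
      i <- match(row$in2, netlist$node[netlist$type == "INPUT"])
      if (s$mode == "activator") s$alpha
      else if (bits[i]) s$alpha else s$alpha * s$beta
    } else {
      g2 <- library$gates[library$gates$name == assignment$node_to_gate[[row$in2]], ]
      x2 <- oracle_input_of(netlist, assignment, library, bits, row$in2, model)
      g2$alpha * (g2$K^g2$n + g2$beta * x2^g2$n) / (g2$K^g2$n + x2^g2$n)
    }
  }
  occ2 * up + down
}

# ---- random structures ------------------------------------------------------

random_netlist <- function(n_inputs = sample(1:3, 1), n_gates = sample(1:4, 1),
                           sensors = c("P_Tac", "P_Tet", "P_Lux2", "P_Cin")) {
  nodes <- tibble::tibble(
    node = paste0("x", seq_len(n_inputs)), type = "INPUT",
    in1 = NA_character_, in2 = NA_character_,
    sensor = sensors[seq_len(n_inputs)]
  )
  for (k in seq_len(n_gates)) {
    avail <- nodes$node
    if (length(avail) >= 2 && stats::runif(1) < 0.5) {
      par <- sample(avail, 2)
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        node = paste0("g", k), type = "NOR2", in1 = par[1], in2 = par[2],
        sensor = NA_character_))
    } else {
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        node = paste0("g", k), type = "NOT", in1 = sample(avail, 1),
        in2 = NA_character_, sensor = NA_character_))
    }
  }
  gates <- nodes$node[nodes$type %in% c("NOT", "NOR2")]
  drivers <- if (length(gates) >= 2 && stats::runif(1) < 0.5)
    sample(gates, 2) else sample(gates, 1)
  nodes <- dplyr::bind_rows(nodes, tibble::tibble(
    node = "out", type = "OUTPUT", in1 = drivers[1],
    in2 = if (length(drivers) > 1) drivers[2] else NA_character_,
    sensor = NA_character_))
  circuit_netlist(nodes)
}

random_assignment <- function(netlist, library) {
  gate_nodes <- netlist$node[netlist$type %in% c("NOT", "NOR2")]
  g <- library$gates
  repeat {
    idx <- sample(nrow(g), length(gate_nodes))
    if (anyDuplicated(g$family[idx])) next
    fams <- g$family[idx]
    bad <- any(vapply(library$layout$prohibited_pairs,
                      function(p) all(p %in% fams), logical(1)))
    if (!bad) return(new_assignment(stats::setNames(g$name[idx], gate_nodes)))
  }
}

random_library <- function(n_gates = 5, n_sensors = 2) {
  fams <- paste0("Fam", seq_len(n_gates))
  gates <- dplyr::bind_rows(lapply(seq_len(n_gates), function(i) {
    y_min <- stats::runif(1, 0.001, 0.1)
    gate_record(paste0("G", i, "-", fams[i]), fams[i],
                y_min = y_min, y_max = y_min + stats::runif(1, 0.5, 7),
                K = stats::runif(1, 0.02, 0.6), n = stats::runif(1, 1, 4.5),
                alpha = stats::runif(1, 0.05, 1), beta = stats::runif(1, 0.05, 1),
                tau_on = stats::runif(1, 0.1, 8), tau_off = stats::runif(1, 0.5, 11))
  }))
  sensors <- dplyr::bind_rows(lapply(seq_len(n_sensors), function(i) {
    off <- stats::runif(1, 0.001, 0.05)
    sensor_record(paste0("S", i), off_rpu = off,
                  on_rpu = off + stats::runif(1, 1, 3),
                  alpha = stats::runif(1, 0.2, 1), beta = stats::runif(1, 0.2, 1),
                  tau_induction = stats::runif(1, 0.5, 4),
                  mode = sample(c("repressor", "activator"), 1))
  }))
  gate_library(gates = gates, sensors = sensors,
               layout = layout_rules(gate_order = fams,
                                     scar_order = c("A", "B", "D", "C"),
                                     prohibited_pairs = if (n_gates >= 2)
                                       list(fams[1:2]) else list()),
               metadata = list(version = "random"))
}

# Library with every interference parameter forced to 1 (additive limit).
additive_limit_library <- function(library = builtin_library()) {
  library$gates$alpha <- 1
  library$gates$beta <- 1
  library$sensors$alpha <- 1
  library$sensors$beta <- 1
  library
}

# ---- brute-force minimum-gate synthesis (oracle) ----------------------------
# Exhaustively enumerates DAG netlists with up to `max_gates` gates over the
# {NOT, NOR2} basis with a free 1- or 2-driver OR output stage, and returns
# the smallest gate count realizing the spec (or Inf). Signatures are bit
# vectors over the 2^n states.
oracle_min_gates <- function(spec, max_gates = 4) {
  n <- attr(spec, "n_inputs")
  states <- 0:(2^n - 1)
  care <- spec$output != "X"
  target <- spec$output == "1"
  matches <- function(sig) all(sig[care] == target[care])
  in_sigs <- lapply(seq_len(n), function(i)
    bitwAnd(bitwShiftR(states, i - 1L), 1L) == 1L)

  out_ok <- function(sigs) {
    for (i in seq_along(sigs)) {
      if (matches(sigs[[i]])) return(TRUE)
      if (i > 1) for (j in seq_len(i - 1))
        if (matches(sigs[[i]] | sigs[[j]])) return(TRUE)
    }
    FALSE
  }
  if (out_ok(in_sigs)) return(0L)

  grow <- function(sigs, k) {
    if (k == 0) return(out_ok(sigs))
    m <- length(sigs)
    for (a in seq_len(m)) {
      if (grow(c(sigs, list(!sigs[[a]])), k - 1)) return(TRUE)   # NOT
      if (a > 1) for (b in seq_len(a - 1)) {
        if (grow(c(sigs, list(!(sigs[[a]] | sigs[[b]]))), k - 1)) return(TRUE)
      }
    }
    FALSE
  }
  for (k in seq_len(max_gates)) {
    if (grow(in_sigs, k)) return(k)
  }
  Inf
}

# ---- brute-force assignment arg-max (oracle) --------------------------------
oracle_best_assignment <- function(netlist, library, spec,
                                   model = "interference") {
  gate_nodes <- netlist$node[netlist$type %in% c("NOT", "NOR2")]
  g <- library$gates
  combos <- expand.grid(rep(list(seq_len(nrow(g))), length(gate_nodes)))
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    idx <- as.integer(combos[r, ])
    fams <- g$family[idx]
    if (anyDuplicated(fams)) next
    if (any(vapply(library$layout$prohibited_pairs,
                   function(p) all(p %in% fams), logical(1)))) next
    asg <- new_assignment(stats::setNames(g$name[idx], gate_nodes))
    tab <- truth_table_prediction(netlist, asg, library, model = model,
                                  spec = spec)
    sc <- circuit_score(tab)
    if (sc > best) best <- sc
  }
  best
}

# Small standard circuits used across test files.
nand_netlist <- function() {
  circuit_netlist(tibble::tibble(
    node = c("x1", "x2", "g_up", "g_down", "out"),
    type = c("INPUT", "INPUT", "NOT", "NOT", "OUTPUT"),
    in1 = c(NA, NA, "x1", "x2", "g_up"),
    in2 = c(NA, NA, NA, NA, "g_down"),
    sensor = c("P_Tac", "P_Tet", NA, NA, NA)
  ))
}

single_gate_netlist <- function(sensor = "P_Tac") {
  circuit_netlist(tibble::tibble(
    node = c("x1", "g1", "out"), type = c("INPUT", "NOT", "OUTPUT"),
    in1 = c(NA, "x1", "g1"), in2 = NA_character_,
    sensor = c(sensor, NA, NA)
  ))
}
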