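#' Create a gate assignment
#'
#' Wraps a named mapping from netlist gate nodes (`NOT`/`NOR2`) to library
#' gate names. Feasibility (one gate per repressor family, no prohibited
#' family pair) is checked by [check_feasible()]; [optimize_assignment()]
#' only ever returns feasible assignments.
#'
#' @param node_to_gate Named character vector: `node id -> gate name`.
#' @param score Optional separation score attached by the optimizer.
#' @param details Optional list of optimizer metadata (method, seed, model).
#' @return A `"gate_assignment"`.
#' @export
new_assignment <- function(node_to_gate, score = NA_real_, details = list()) {
  structure(
    list(node_to_gate = node_to_gate[sort(names(node_to_gate))],
         score = score, details = details),
    class = "gate_assignment"
  )
}

#' @export
print.gate_assignment <- function(x, ...) {
  cat("<gate_assignment>", length(x$node_to_gate), "nodes")
  if (!is.na(x$score)) cat(", score", format(x$score, digits = 4))
  cat("\n")
  for (nm in names(x$node_to_gate))
    cat("  ", nm, " -> ", x$node_to_gate[[nm]], "\n", sep = "")
  invisible(x)
}

#' Check assignment feasibility
#'
#' An assignment is feasible when no two nodes use gates of the same
#' repressor family (same-family gates only differ by RBS and would
#' cross-react) and no prohibited family pair (insufficiently orthogonal
#' repressors) is co-present.
#'
#' @param assignment A `"gate_assignment"`.
#' @param library A `"gate_library"`.
#' @return `check_feasible()` returns a tibble of violations (columns `rule`,
#'   `detail`); `is_feasible()` returns a single logical.
#' @export
check_feasible <- function(assignment, library) {
  gates <- unname(assignment$node_to_gate)
  fams <- vapply(gates, function(g) lib_gate(library, g)$family, character(1))
  viol <- list()
  dup <- unique(fams[duplicated(fams)])
  for (f in dup) {
    viol[[length(viol) + 1]] <- tibble::tibble(
      rule = "same_family_once",
      detail = paste0("family ", f, " used by: ",
                      paste(gates[fams == f], collapse = ", ")))
  }
  for (p in library$layout$prohibited_pairs) {
    if (all(p %in% fams)) {
      viol[[length(viol) + 1]] <- tibble::tibble(
        rule = "prohibited_pair",
        detail = paste0("families ", paste(p, collapse = " and "),
                        " may not co-occur"))
    }
  }
  if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(rule = character(), detail = character())
}

#' @rdname check_feasible
#' @export
is_feasible <- function(assignment, library) {
  nrow(check_feasible(assignment, library)) == 0
}

# Fast score of a raw node->gate mapping (no per-state tibbles built).
score_mapping <- function(netlist, node_to_gate, library, spec, model) {
  res <- evaluate_states_core(netlist, list(node_to_gate = node_to_gate),
                              library, spec$state, model)
  on <- res$output[spec$output == "1"]
  off <- res$output[spec$output == "0"]
  min(on) / max(off)
}

# Enumerate which gates each node may take so that families stay injective
# and prohibited pairs absent; recursion in canonical (library) order.
exhaustive_best <- function(netlist, gate_nodes, library, spec, model) {
  g <- library$gates
  prohibited <- library$layout$prohibited_pairs
  best_score <- -Inf
  best_map <- NULL
  k <- length(gate_nodes)
  chosen <- character(k)
  fams <- character(k)

  recurse <- function(depth) {
    if (depth > k) {
      map <- stats::setNames(chosen, gate_nodes)
      sc <- score_mapping(netlist, map, library, spec, model)
      if (sc > best_score) {          # strict: first (canonical) wins ties
        best_score <<- sc
        best_map <<- map
      }
      return(invisible(NULL))
    }
    used <- fams[seq_len(depth - 1)]
    for (i in seq_len(nrow(g))) {
      f <- g$family[i]
      if (f %in% used) next
      blocked <- any(vapply(prohibited, function(p)
        f %in% p && any(setdiff(p, f) %in% used), logical(1)))
      if (blocked) next
      chosen[depth] <<- g$name[i]
      fams[depth] <<- f
      recurse(depth + 1)
    }
  }
  recurse(1)
  if (is.null(best_map))
    abort("No feasible assignment exists for this netlist and library.",
          class = "norcircuit_capacity_error")
  list(map = best_map, score = best_score)
}

random_feasible_map <- function(gate_nodes, library) {
  g <- library$gates
  prohibited <- library$layout$prohibited_pairs
  repeat {
    idx <- sample(nrow(g), length(gate_nodes))
    fams <- g$family[idx]
    if (anyDuplicated(fams)) next
    if (any(vapply(prohibited, function(p) all(p %in% fams), logical(1)))) next
    return(stats::setNames(g$name[idx], gate_nodes))
  }
}

anneal_best <- function(netlist, gate_nodes, library, spec, model,
                        steps, cooling) {
  g <- library$gates
  current <- random_feasible_map(gate_nodes, library)
  cur_score <- score_mapping(netlist, current, library, spec, model)
  best <- current; best_score <- cur_score

  # initial temperature from the score spread of 100 random assignments
  probe <- vapply(1:100, function(i)
    score_mapping(netlist, random_feasible_map(gate_nodes, library),
                  library, spec, model), numeric(1))
  temp <- max(stats::sd(probe), 1e-6)

  k <- length(gate_nodes)
  for (step in seq_len(steps)) {
    prop <- current
    if (k >= 2 && stats::runif(1) < 0.5) {       # swap two nodes' gates
      ij <- sample(k, 2)
      prop[ij] <- prop[rev(ij)]
    } else {                                     # reassign one node
      node <- sample(k, 1)
      fams <- vapply(prop[-node], function(nm) lib_gate(library, nm)$family,
                     character(1))
      ok <- !(g$family %in% fams) & (g$name != prop[[node]])
      for (p in library$layout$prohibited_pairs) {
        if (p[1] %in% fams) ok <- ok & g$family != p[2]
        if (p[2] %in% fams) ok <- ok & g$family != p[1]
      }
      if (!any(ok)) next
      prop[[node]] <- sample(g$name[ok], 1)
    }
    sc <- score_mapping(netlist, prop, library, spec, model)
    if (sc >= cur_score || stats::runif(1) < exp((sc - cur_score) / temp)) {
      current <- prop; cur_score <- sc
      if (sc > best_score) { best <- prop; best_score <- sc }
    }
    temp <- temp * cooling
  }
  list(map = best, score = best_score)
}

#' Optimize the assignment of library gates to a netlist
#'
#' Searches for the feasible assignment maximizing the circuit separation
#' score ([circuit_score()]). Small instances are solved exhaustively
#' (enumerating every feasible assignment; ties broken by canonical
#' library-order enumeration); larger ones by seeded simulated annealing
#' whose proposals either reassign one node or swap the gates of two nodes,
#' with geometric cooling. `method = "auto"` switches at a
#' feasible-assignment-count threshold.
#'
#' @param netlist A `"circuit_netlist"`.
#' @param library A `"gate_library"`; must offer at least as many repressor
#'   families as the netlist has gate nodes.
#' @param model Composition model used for scoring (`"interference"` by
#'   default — additive on request).
#' @param method `"auto"`, `"exhaustive"` or `"anneal"`.
#' @param seed Integer seed controlling annealing (ignored by exhaustive
#'   search); the same seed always yields the same assignment.
#' @param spec Optional `"truth_spec"` defining required ON/OFF states for
#'   scoring (don't-care rows are excluded); defaults to the netlist's exact
#'   Boolean function via [netlist_truth_table()].
#' @param options List of tuning knobs: `steps` (annealing steps, default
#'   10000), `cooling` (geometric factor, default 0.98), `threshold`
#'   (feasible-count bound for `"auto"`, default 1e6).
#' @return A `"gate_assignment"` with its `score` and optimizer `details`.
#' @export
optimize_assignment <- function(netlist, library,
                                model = c("interference", "additive"),
                                method = c("auto", "exhaustive", "anneal"),
                                seed = 1L, spec = NULL, options = list()) {
  model <- match.arg(model)
  method <- match.arg(method)
  opts <- utils::modifyList(
    list(steps = 10000L, cooling = 0.98, threshold = 1e6), options)
  gate_nodes <- netlist$node[netlist$type %in% c("NOT", "NOR2")]
  if (length(gate_nodes) == 0)
    abort("Netlist has no gate nodes to assign.")
  n_fam <- length(unique(library$gates$family))
  if (length(gate_nodes) > n_fam)
    abort(paste0("Netlist needs ", length(gate_nodes),
                 " distinct repressor families but the library offers ",
                 n_fam, "."),
          class = "norcircuit_capacity_error")
  if (is.null(spec)) spec <- netlist_truth_table(netlist)
  if (!any(spec$output == "1") || !any(spec$output == "0"))
    abort("Scoring spec needs at least one ON and one OFF state.")

  if (method == "auto") {
    # upper bound on feasible count: ordered gate selections
    bound <- prod(nrow(library$gates) - seq_along(gate_nodes) + 1)
    method <- if (bound <= opts$threshold) "exhaustive" else "anneal"
  }

  if (method == "exhaustive") {
    res <- exhaustive_best(netlist, gate_nodes, library, spec, model)
  } else {
    res <- with_local_seed(seed, anneal_best(
      netlist, gate_nodes, library, spec, model, opts$steps, opts$cooling))
  }
  new_assignment(res$map, score = res$score,
                 details = list(method = method, seed = seed, model = model,
                                steps = if (method == "anneal") opts$steps))
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Linear DNA layout of an assignment
#'
#' Orders the assigned gates by the enforced repressor-family order and
#' attaches type-IIS cloning scars: scar `A` always leftmost, scar `C`
#' always rightmost, and the intermediate scars consumed in their declared
#' order between consecutive gates.
#'
#' @param assignment A feasible `"gate_assignment"` with at least one gate.
#' @param library A `"gate_library"` providing `layout` rules.
#' @return A `"layout_plan"` tibble with columns `kind` (`"scar"`/`"gate"`)
#'   and `label`, in left-to-right construct order.
#' @export
#' @examples
#' lib <- builtin_library()
#' asg <- new_assignment(c(g1 = "P1-PhlF", g2 = "A1-AmtR_2"))
#' layout_plan(asg, lib)
layout_plan <- function(assignment, library) {
  gates <- unname(assignment$node_to_gate)
  if (length(gates) == 0) abort("Cannot lay out an empty assignment.")
  viol <- check_feasible(assignment, library)
  if (nrow(viol) > 0)
    abort(c("Assignment is infeasible:", viol$detail))
  fams <- vapply(gates, function(g) lib_gate(library, g)$family, character(1))
  order_rule <- library$layout$gate_order
  missing <- setdiff(fams, order_rule)
  if (length(missing))
    abort(paste0("Layout rule error: family not in enforced gate order: ",
                 paste(missing, collapse = ", ")))
  gates <- gates[order(match(fams, order_rule))]

  scars <- library$layout$scar_order
  inner <- scars[-c(1, length(scars))]
  if (length(gates) - 1 > length(inner))
    abort("Layout rule error: not enough cloning scars for this many gates.")
  labels <- character(0)
  kinds <- character(0)
  for (i in seq_along(gates)) {
    labels <- c(labels, if (i == 1) "A" else inner[i - 1], gates[i])
    kinds <- c(kinds, "scar", "gate")
  }
  labels <- c(labels, "C")
  kinds <- c(kinds, "scar")
  out <- tibble::tibble(kind = kinds, label = labels)
  class(out) <- c("layout_plan", class(tibble::tibble()))
  out
}
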