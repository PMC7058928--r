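#' Full design pipeline: truth table to laid-out, scored circuit
#'
#' Chains the design-automation steps: [synthesize()] a NOT/NOR netlist
#' from the truth spec, [optimize_assignment()] of library gates,
#' [layout_plan()] for the linear DNA order, and [truth_table_prediction()]
#' for the predicted state table and separation score.
#'
#' @param spec A `"truth_spec"`.
#' @param library A `"gate_library"` (default [builtin_library()]).
#' @param model Composition model for scoring and prediction.
#' @param method,seed,options Passed to [optimize_assignment()].
#' @param max_gates Gate budget for synthesis.
#' @return A list of class `"circuit_design"` with elements `netlist`,
#'   `assignment`, `layout`, `prediction` (a `"state_table"`) and `score`.
#' @export
#' @examples
#' \donttest{
#' d <- design_circuit(truth_spec(c("1", "1", "1", "0")), seed = 1)
#' d$score
#' }
design_circuit <- function(spec, library = builtin_library(),
                           model = c("interference", "additive"),
                           method = c("auto", "exhaustive", "anneal"),
                           seed = 1L, max_gates = 12, options = list()) {
  model <- match.arg(model)
  method <- match.arg(method)
  netlist <- synthesize(spec, max_gates = max_gates)
  assignment <- optimize_assignment(netlist, library, model = model,
                                    method = method, seed = seed, spec = spec,
                                    options = options)
  layout <- layout_plan(assignment, library)
  prediction <- truth_table_prediction(netlist, assignment, library,
                                       model = model, spec = spec)
  structure(
    list(netlist = netlist, assignment = assignment, layout = layout,
         prediction = prediction, score = circuit_score(prediction),
         model = model, seed = seed),
    class = "circuit_design"
  )
}

#' @export
print.circuit_design <- function(x, ...) {
  cat("<circuit_design> ", n_gates(x$netlist), " gates, model = ", x$model,
      ", score = ", format(x$score, digits = 4), "\n", sep = "")
  print(x$assignment)
  invisible(x)
}

#' Convert optical density to colony-forming units
#'
#' Plate-reader calibration for loading display chambers with a defined
#' cell number: `CFU/ml = 2e9 * OD600^0.9759`.
#'
#' @param od600 Measured optical density at 600 nm (non-negative,
#'   vectorized).
#' @return Colony-forming units per ml.
#' @export
#' @examples
#' od_to_cfu(1.0)   # 2e9
od_to_cfu <- function(od600) {
  if (any(od600 < 0)) abort("`od600` must be non-negative.")
  2e9 * od600^0.9759
}
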