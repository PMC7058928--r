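#' Construct a circuit netlist
#'
#' A netlist is the acyclic wiring diagram of a transcriptional circuit. It
#' is stored as a tibble with one row per node and columns:
#'
#' * `node` — unique identifier
#' * `type` — `"INPUT"`, `"NOT"`, `"NOR2"` or `"OUTPUT"`
#' * `in1` — parent node in the upstream tandem position (position 1), or `NA`
#' * `in2` — parent node in the downstream tandem position (position 2), or `NA`
#' * `sensor` — sensor bound to an `INPUT` node, `NA` otherwise
#'
#' For a `NOR2` node the two parents' output promoters sit in tandem in front
#' of the repressor gene: the `in2` (downstream) promoter can roadblock RNAP
#' originating from the `in1` (upstream) promoter. A `NOT` node has a single
#' input promoter (`in1`). The single `OUTPUT` node models the reporter
#' stage; with two drivers it is a tandem-promoter OR, composed with the same
#' interference rule as a `NOR2` input pair.
#'
#' The i-th `INPUT` row (in row order) is circuit input i; input 1 is the
#' least-significant bit of the state index.
#'
#' @param nodes A data frame with the columns above (`in2`/`sensor` may be
#'   omitted if entirely `NA`).
#' @return A `"circuit_netlist"` tibble, rows in topological order.
#' @export
#' @examples
#' # NOT gate reading sensor P_Tac
#' circuit_netlist(tibble::tibble(
#'   node = c("x1", "g1", "out"),
#'   type = c("INPUT", "NOT", "OUTPUT"),
#'   in1  = c(NA, "x1", "g1"),
#'   sensor = c("P_Tac", NA, NA)
#' ))
circuit_netlist <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (!"in2" %in% names(nodes)) nodes$in2 <- NA_character_
  if (!"sensor" %in% names(nodes)) nodes$sensor <- NA_character_
  nodes <- nodes[, c("node", "type", "in1", "in2", "sensor")]
  nodes$node <- as.character(nodes$node)
  nodes$in1 <- as.character(nodes$in1)
  nodes$in2 <- as.character(nodes$in2)
  nodes$sensor <- as.character(nodes$sensor)

  if (anyDuplicated(nodes$node))
    abort("Netlist structural error: duplicate node ids.")
  bad_type <- setdiff(nodes$type, c("INPUT", "NOT", "NOR2", "OUTPUT"))
  if (length(bad_type))
    abort(paste0("Netlist structural error: unknown node type(s): ",
                 paste(bad_type, collapse = ", ")))

  for (i in seq_len(nrow(nodes))) {
    r <- nodes[i, ]
    n_par <- sum(!is.na(c(r$in1, r$in2)))
    ok <- switch(r$type,
      INPUT  = n_par == 0 && !is.na(r$sensor),
      NOT    = n_par == 1 && !is.na(r$in1),
      NOR2   = n_par == 2 && !identical(r$in1, r$in2),
      OUTPUT = n_par >= 1 && !is.na(r$in1)
    )
    if (!ok) abort(paste0("Netlist arity error at node '", r$node, "' (",
                          r$type, "): wrong number of parents",
                          if (r$type == "INPUT") " or missing sensor binding"))
    parents <- stats::na.omit(c(r$in1, r$in2))
    unknown <- setdiff(parents, nodes$node)
    if (length(unknown))
      abort(paste0("Netlist structural error: node '", r$node,
                   "' references unknown parent(s): ",
                   paste(unknown, collapse = ", ")))
  }
  if (sum(nodes$type == "OUTPUT") != 1)
    abort("Netlist structural error: exactly one OUTPUT node is required.")
  if (sum(nodes$type == "INPUT") < 1)
    abort("Netlist structural error: at least one INPUT node is required.")

  order <- netlist_topo_order(nodes)      # errors on cycles
  nodes <- nodes[match(order, nodes$node), ]

  # Every non-INPUT node must be reachable from some INPUT (equivalently,
  # in this parent-pointer representation: every non-INPUT node's ancestor
  # closure contains an INPUT).
  reach <- stats::setNames(nodes$type == "INPUT", nodes$node)
  for (i in seq_len(nrow(nodes))) {
    r <- nodes[i, ]
    if (r$type == "INPUT") next
    parents <- stats::na.omit(c(r$in1, r$in2))
    reach[r$node] <- any(reach[parents])
  }
  if (!all(reach))
    abort(paste0("Netlist structural error: node(s) not fed by any input: ",
                 paste(names(reach)[!reach], collapse = ", ")))

  class(nodes) <- c("circuit_netlist", class(tibble::tibble()))
  nodes
}

# Kahn topological sort over parent pointers; abort on cycles (incl. self-loops).
netlist_topo_order <- function(nodes) {
  ids <- nodes$node
  parents <- lapply(seq_len(nrow(nodes)), function(i)
    stats::na.omit(c(nodes$in1[i], nodes$in2[i])))
  names(parents) <- ids
  indeg <- vapply(parents, length, integer(1))
  order <- character(0)
  ready <- ids[indeg == 0]
  while (length(ready)) {
    nxt <- sort(ready)[1]                       # deterministic order
    ready <- setdiff(ready, nxt)
    order <- c(order, nxt)
    for (id in ids) {
      if (nxt %in% parents[[id]]) {
        parents[[id]] <- setdiff(parents[[id]], nxt)
        if (length(parents[[id]]) == 0 && !(id %in% order)) {
          ready <- union(ready, id)
        }
      }
    }
  }
  if (length(order) != length(ids))
    abort(paste0("Netlist structural error: cycle involving node(s): ",
                 paste(setdiff(ids, order), collapse = ", ")))
  # keep INPUTs in their original row order so input indexing is stable
  inputs <- ids[nodes$type == "INPUT"]
  c(inputs, setdiff(order, inputs))
}

netlist_inputs <- function(netlist) {
  netlist$node[netlist$type == "INPUT"]
}

netlist_output <- function(netlist) {
  netlist$node[netlist$type == "OUTPUT"]
}

#' Number of gates in a netlist
#'
#' Counts the repressor gates (`NOT` and `NOR2` nodes); inputs and the
#' reporter output stage carry no repressor.
#'
#' @param netlist A `"circuit_netlist"`.
#' @return Integer gate count.
#' @export
n_gates <- function(netlist) {
  sum(netlist$type %in% c("NOT", "NOR2"))
}

#' Read / write a netlist file
#'
#' The netlist text format is line-oriented and tab-separated:
#' `node<TAB>type<TAB>parents<TAB>sensor`, where `parents` is `-` or a
#' comma-separated list (first entry = tandem position 1 / upstream, second =
#' position 2 / downstream) and `sensor` is `-` except on `INPUT` nodes.
#' Blank lines and lines starting with `#` are ignored. Cycles and arity
#' violations are rejected at parse time.
#'
#' @param path File path.
#' @return For `parse_netlist`, a `"circuit_netlist"`; `write_netlist`
#'   returns `path` invisibly.
#' @export
parse_netlist <- function(path) {
  if (!file.exists(path)) abort(paste0("Netlist file not found: ", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  rows <- purrr::map(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 4)
      abort(paste0("Netlist parse error at line ", i,
                   ": expected 4 tab-separated fields, found ", length(fields)))
    parents <- if (fields[3] == "-") character(0) else
      strsplit(fields[3], ",", fixed = TRUE)[[1]]
    if (length(parents) > 2)
      abort(paste0("Netlist parse error at line ", i,
                   ": more than two parents."))
    tibble::tibble(
      node = fields[1], type = fields[2],
      in1 = if (length(parents) >= 1) parents[1] else NA_character_,
      in2 = if (length(parents) >= 2) parents[2] else NA_character_,
      sensor = if (fields[4] == "-") NA_character_ else fields[4]
    )
  })
  circuit_netlist(dplyr::bind_rows(rows))
}

#' @rdname parse_netlist
#' @param netlist A `"circuit_netlist"`.
#' @export
write_netlist <- function(netlist, path) {
  stopifnot(inherits(netlist, "circuit_netlist"))
  lines <- purrr::pmap_chr(netlist, function(node, type, in1, in2, sensor) {
    parents <- stats::na.omit(c(in1, in2))
    paste(node, type,
          if (length(parents)) paste(parents, collapse = ",") else "-",
          if (is.na(sensor)) "-" else sensor,
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Boolean semantics of a netlist
#'
#' Evaluates the exact digital logic of a netlist over all input states:
#' `NOT` is logical negation, `NOR2` is the negation of OR, and a two-driver
#' tandem `OUTPUT` stage is the OR of its drivers. This is the verification
#' oracle used to check that a synthesized netlist realizes its
#' specification.
#'
#' @param netlist A `"circuit_netlist"`.
#' @return A `"truth_spec"` tibble (columns `state`, `bits`, `output`),
#'   with no don't-care rows.
#' @export
netlist_truth_table <- function(netlist) {
  inputs <- netlist_inputs(netlist)
  n <- length(inputs)
  states <- 0:(2^n - 1)
  vals <- list()
  for (i in seq_len(nrow(netlist))) {
    r <- netlist[i, ]
    vals[[r$node]] <- switch(r$type,
      INPUT  = bitwAnd(bitwShiftR(states, match(r$node, inputs) - 1L), 1L) == 1L,
      NOT    = !vals[[r$in1]],
      NOR2   = !(vals[[r$in1]] | vals[[r$in2]]),
      OUTPUT = if (is.na(r$in2)) vals[[r$in1]] else vals[[r$in1]] | vals[[r$in2]]
    )
  }
  # built directly (not via truth_spec()) because a netlist may legitimately
  # compute a constant function, which a design spec may not request
  outputs <- ifelse(vals[[netlist_output(netlist)]], "1", "0")
  out <- tibble::tibble(state = states, bits = state_bits_chr(states, n),
                        output = outputs)
  class(out) <- c("truth_spec", class(tibble::tibble()))
  attr(out, "n_inputs") <- as.integer(n)
  out
}
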