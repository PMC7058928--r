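#' Construct a truth-table specification
#'
#' A truth spec fixes the required circuit output for each input bit-vector:
#' `"1"` (ON), `"0"` (OFF) or `"X"` (don't-care). States are indexed in
#' canonical binary order with input 1 as the least-significant bit.
#'
#' @param outputs Character (or 0/1 numeric) vector of length `2^n_inputs`
#'   with entries `"0"`, `"1"`, `"X"`; at least one `"0"` and one `"1"`.
#' @return A `"truth_spec"` tibble with columns `state`, `bits`, `output`.
#' @export
#' @examples
#' truth_spec(c("1", "0"))            # NOT
#' truth_spec(c("1", "0", "0", "0"))  # NOR2
truth_spec <- function(outputs) {
  outputs <- toupper(as.character(outputs))
  if (!all(outputs %in% c("0", "1", "X")))
    abort("Truth spec entries must be '0', '1' or 'X'.")
  n <- log2(length(outputs))
  if (length(outputs) < 2 || n != round(n) || n > 4)
    abort("Truth spec length must be 2^n for n in 1..4.")
  n <- as.integer(n)
  if (!any(outputs == "1") || !any(outputs == "0"))
    abort("Truth spec needs at least one required-ON and one required-OFF row.")
  out <- tibble::tibble(
    state = 0:(length(outputs) - 1L),
    bits = state_bits_chr(0:(length(outputs) - 1L), n),
    output = outputs
  )
  class(out) <- c("truth_spec", class(tibble::tibble()))
  attr(out, "n_inputs") <- n
  out
}

#' Read / write a truth-spec file
#'
#' Tab-separated rows `bits<TAB>output` where `bits` is the input bit-vector
#' written most-significant-input first (so `0100` with 4 inputs means only
#' input 3 is on) and `output` is `0`, `1` or `X`. Rows may appear in any
#' order but must cover every state exactly once.
#'
#' @param path File path.
#' @return For `read_truth_spec`, a `"truth_spec"`; `write_truth_spec`
#'   returns `path` invisibly.
#' @export
read_truth_spec <- function(path) {
  if (!file.exists(path)) abort(paste0("Truth-spec file not found: ", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  rows <- purrr::map(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2)
      abort(paste0("Truth-spec parse error at line ", i,
                   ": expected 'bits<TAB>output'."))
    tibble::tibble(state = strtoi(fields[1], base = 2L), output = fields[2])
  })
  df <- dplyr::bind_rows(rows)
  if (anyDuplicated(df$state) || !setequal(df$state, 0:(nrow(df) - 1L)))
    abort("Truth-spec parse error: states must cover 0..2^n-1 exactly once.")
  truth_spec(df$output[order(df$state)])
}

#' @rdname read_truth_spec
#' @param spec A `"truth_spec"`.
#' @export
write_truth_spec <- function(spec, path) {
  writeLines(paste(spec$bits, spec$output, sep = "\t"), path)
  invisible(path)
}

#' Seven-segment decoder truth tables
#'
#' The BCD-to-7-segment decoder maps a 4-bit binary-coded digit (inputs 1-4,
#' input 1 = least-significant bit) to the on/off state of display segments
#' A-G. The packaged tables use the classic decoder-chip renderings (digit 6
#' without the top segment, digit 9 without the bottom segment); input
#' states 10-15 fall outside the decimal range and are don't-care by
#' default.
#'
#' @param segment One of `"A"` .. `"G"`.
#' @param undefined_digits Output required for states 10-15: `"X"`
#'   (default), `"0"` or `"1"`.
#' @return A `"truth_spec"` with 16 rows.
#' @export
#' @examples
#' segment_spec("A")
segment_spec <- function(segment = c("A", "B", "C", "D", "E", "F", "G"),
                         undefined_digits = "X") {
  segment <- match.arg(segment)
  on_digits <- list(
    A = c(0, 2, 3, 5, 7, 8, 9),
    B = c(0, 1, 2, 3, 4, 7, 8, 9),
    C = c(0, 1, 3, 4, 5, 6, 7, 8, 9),
    D = c(0, 2, 3, 5, 6, 8),
    E = c(0, 2, 6, 8),
    F = c(0, 4, 5, 6, 8, 9),
    G = c(2, 3, 4, 5, 6, 8, 9)
  )[[segment]]
  out <- rep("0", 16)
  out[on_digits + 1] <- "1"
  out[11:16] <- undefined_digits
  truth_spec(out)
}

# ---- exact synthesis over the {NOT, NOR2} basis -----------------------------
#
# Signatures are 2^n-bit integers: bit s holds the Boolean output for input
# state s. The search is a breadth-first sweep over total gate count with
# signature memoization: cost-0 signatures are the inputs; each level adds
# NOT of the previous level and NOR2 of every cost-split pair. A realization
# is accepted when a signature (or the OR of two signatures, realized for
# free by the tandem reporter stage) matches the spec on all care bits.

input_signatures <- function(n) {
  states <- 0:(2^n - 1)
  vapply(seq_len(n), function(i)
    sum(bitwShiftL(bitwAnd(bitwShiftR(states, i - 1L), 1L), states)),
    numeric(1))
}

#' Synthesize a NOT/NOR netlist from a truth table
#'
#' Finds a netlist of `NOT`/`NOR2` gates (plus, optionally, a two-driver
#' tandem-OR reporter stage, which costs no gate) whose Boolean function
#' matches the spec on every non-don't-care row, using the fewest gates
#' found within `max_gates`. The search is an exhaustive breadth-first sweep
#' over gate counts with truth-table-signature memoization, so the result is
#' a true minimum-formula realization; identical subexpressions are merged
#' into shared nodes afterwards. Output is deterministic for a given spec:
#' ties are broken by fewest `NOT` nodes, then shallowest depth, then
#' canonical signature order.
#'
#' @param spec A `"truth_spec"`.
#' @param max_gates Gate budget (default 12).
#' @param mode `"enumerate"` (default) or `"minimize"`; both run the same
#'   exact search (the enumerative sweep already returns a minimum, so no
#'   pre-simplification pass is needed).
#' @param input_sensors Sensor names bound to inputs 1..n; defaults to the
#'   decoder wiring `P_Lux2`, `P_Tet`, `P_Cin`, `P_Tac`.
#' @return A `"circuit_netlist"`.
#' @export
#' @examples
#' nand <- truth_spec(c("1", "1", "1", "0"))
#' synthesize(nand)   # two NOT gates with a tandem-OR output stage
synthesize <- function(spec, max_gates = 12,
                       mode = c("enumerate", "minimize"),
                       input_sensors = NULL) {
  mode <- match.arg(mode)
  if (max_gates < 1) abort("`max_gates` must be at least 1.")
  n <- attr(spec, "n_inputs")
  nbits <- 2^n
  if (is.null(input_sensors))
    input_sensors <- c("P_Lux2", "P_Tet", "P_Cin", "P_Tac")[seq_len(n)]
  if (length(input_sensors) != n)
    abort("`input_sensors` must name one sensor per input.")

  care <- sum(bitwShiftL(as.integer(spec$output != "X"), spec$state))
  target <- sum(bitwShiftL(as.integer(spec$output == "1"), spec$state))
  mask <- 2^nbits - 1
  matches <- function(sig) bitwAnd(bitwXor(sig, target), care) == 0L

  ins <- input_signatures(n)
  # memo tables keyed by signature value (as character)
  info <- new.env(parent = emptyenv())
  set_info <- function(sig, op, c1, c2, cost, nnot, depth) {
    assign(as.character(sig),
           list(op = op, c1 = c1, c2 = c2, cost = cost, nnot = nnot,
                depth = depth),
           envir = info)
  }
  get_info <- function(sig) get(as.character(sig), envir = info)
  known <- function(sig) exists(as.character(sig), envir = info)

  levels <- vector("list", max_gates + 1)   # levels[[c+1]] = sigs of cost c
  lev0 <- unique(ins)
  for (s in lev0) {
    i <- match(s, ins)
    set_info(s, "IN", i, NA_real_, 0L, 0L, 0L)
  }
  levels[[1]] <- sort(lev0)

  best <- NULL   # list(drivers = c(sig) or c(sig1, sig2), key = c(nnot, depth, s1, s2))
  consider <- function(drivers) {
    inf <- lapply(drivers, get_info)
    key <- c(sum(vapply(inf, function(z) z$nnot, numeric(1))),
             max(vapply(inf, function(z) z$depth, numeric(1))),
             drivers[1], if (length(drivers) > 1) drivers[2] else -1)
    if (is.null(best) ||
        isTRUE(vec_less(key, best$key))) best <<- list(drivers = drivers, key = key)
  }

  check_solutions_at <- function(cost) {
    # single-driver realizations of exactly this cost
    for (s in levels[[cost + 1]]) if (matches(s)) consider(s)
    # tandem OR of two signatures whose costs sum to this cost
    for (i in 0:floor(cost / 2)) {
      j <- cost - i
      A <- levels[[i + 1]]; B <- levels[[j + 1]]
      if (length(A) == 0 || length(B) == 0) next
      grid_a <- rep(A, times = length(B))
      grid_b <- rep(B, each = length(A))
      keep <- if (i == j) grid_a < grid_b else TRUE
      grid_a <- grid_a[keep]; grid_b <- grid_b[keep]
      ors <- bitwOr(grid_a, grid_b)
      hit <- which(bitwAnd(bitwXor(ors, target), care) == 0L)
      for (k in hit) consider(sort(c(grid_a[k], grid_b[k])))
    }
    !is.null(best)
  }

  if (check_solutions_at(0))
    return(build_netlist_from_sigs(best$drivers, info, n, input_sensors))

  for (cost in seq_len(max_gates)) {
    # candidates of exactly `cost` gates
    cand <- list()
    prev <- levels[[cost]]
    if (length(prev)) {
      pinfo <- lapply(prev, get_info)
      cand[[1]] <- tibble::tibble(
        sig = bitwAnd(bitwNot(prev), mask), op = "NOT", c1 = prev, c2 = NA_real_,
        nnot = vapply(pinfo, function(z) z$nnot, numeric(1)) + 1,
        depth = vapply(pinfo, function(z) z$depth, numeric(1)) + 1
      )
    }
    for (i in 0:floor((cost - 1) / 2)) {
      j <- cost - 1 - i
      A <- levels[[i + 1]]; B <- levels[[j + 1]]
      if (length(A) == 0 || length(B) == 0) next
      grid_a <- rep(A, times = length(B))
      grid_b <- rep(B, each = length(A))
      if (i == j) {
        # NOR(s, s) is just NOT(s); a NOR2 node needs two distinct parents
        keep <- grid_a < grid_b
        grid_a <- grid_a[keep]; grid_b <- grid_b[keep]
      }
      na <- vapply(lapply(A, get_info), function(z) z$nnot, numeric(1))
      nb <- vapply(lapply(B, get_info), function(z) z$nnot, numeric(1))
      da <- vapply(lapply(A, get_info), function(z) z$depth, numeric(1))
      db <- vapply(lapply(B, get_info), function(z) z$depth, numeric(1))
      ga <- rep(seq_along(A), times = length(B))
      gb <- rep(seq_along(B), each = length(A))
      if (i == j) { ga <- ga[keep]; gb <- gb[keep] }
      cand[[length(cand) + 1]] <- tibble::tibble(
        sig = bitwAnd(bitwNot(bitwOr(grid_a, grid_b)), mask),
        op = "NOR", c1 = grid_a, c2 = grid_b,
        nnot = na[ga] + nb[gb],
        depth = pmax(da[ga], db[gb]) + 1
      )
    }
    new_sigs <- numeric(0)
    if (length(cand)) {
      cand <- dplyr::bind_rows(cand)
      cand <- cand[order(cand$nnot, cand$depth, cand$sig, cand$c1, cand$c2), ]
      cand <- cand[!duplicated(cand$sig), ]
      fresh <- !vapply(cand$sig, known, logical(1))
      cand <- cand[fresh, ]
      for (k in seq_len(nrow(cand))) {
        set_info(cand$sig[k], cand$op[k], cand$c1[k], cand$c2[k],
                 cost, cand$nnot[k], cand$depth[k])
      }
      new_sigs <- sort(cand$sig)
    }
    levels[[cost + 1]] <- new_sigs

    if (check_solutions_at(cost))
      return(build_netlist_from_sigs(best$drivers, info, n, input_sensors))
  }

  abort(paste0("No NOT/NOR realization within ", max_gates, " gates (",
               "all signature sets up to that gate count were explored)."),
        class = "norcircuit_capacity_error")
}

vec_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# Reconstruct a netlist from driver signature(s). Identical signatures are
# realized once and shared (common-subexpression merge), so the emitted gate
# count never exceeds the formula cost found by the search.
build_netlist_from_sigs <- function(drivers, info, n, input_sensors) {
  rows <- list()
  node_of <- new.env(parent = emptyenv())
  counter <- 0L

  emit <- function(sig) {
    key <- as.character(sig)
    if (exists(key, envir = node_of)) return(get(key, envir = node_of))
    inf <- get(key, envir = info)
    if (inf$op == "IN") {
      id <- paste0("x", inf$c1)
      rows[[id]] <<- tibble::tibble(node = id, type = "INPUT",
                                    in1 = NA_character_, in2 = NA_character_,
                                    sensor = input_sensors[inf$c1])
    } else if (inf$op == "NOT") {
      p <- emit(inf$c1)
      counter <<- counter + 1L
      id <- sprintf("g%02d", counter)
      rows[[id]] <<- tibble::tibble(node = id, type = "NOT", in1 = p,
                                    in2 = NA_character_, sensor = NA_character_)
    } else {
      p1 <- emit(inf$c1)
      p2 <- emit(inf$c2)
      # deterministic tandem positions: lexicographically smaller id upstream
      ordered <- sort(c(p1, p2))
      counter <<- counter + 1L
      id <- sprintf("g%02d", counter)
      rows[[id]] <<- tibble::tibble(node = id, type = "NOR2", in1 = ordered[1],
                                    in2 = ordered[2], sensor = NA_character_)
    }
    assign(key, id, envir = node_of)
    id
  }

  driver_ids <- vapply(drivers, emit, character(1))
  driver_ids <- sort(unique(driver_ids))
  rows[["out"]] <- tibble::tibble(
    node = "out", type = "OUTPUT",
    in1 = driver_ids[1],
    in2 = if (length(driver_ids) > 1) driver_ids[2] else NA_character_,
    sensor = NA_character_
  )
  # every declared input gets a node even if the minimized logic ignores it,
  # so the netlist's state indexing always matches the spec's bit positions
  for (i in seq_len(n)) {
    id <- paste0("x", i)
    if (is.null(rows[[id]]))
      rows[[id]] <- tibble::tibble(node = id, type = "INPUT",
                                   in1 = NA_character_, in2 = NA_character_,
                                   sensor = input_sensors[i])
  }
  # input rows in input order (input 1 first), then gates, then the output
  ids <- c(paste0("x", seq_len(n)), sort(names(rows)[startsWith(names(rows), "g")]),
           "out")
  circuit_netlist(dplyr::bind_rows(rows[ids]))
}
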