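#' Closed-form single-timescale relaxation
#'
#' Under a constant steady-state target the two-timescale gate ODE reduces
#' to exponential relaxation: `y(t) = y_ss + (y0 - y_ss) * exp(-tau * t)`.
#' Used both as a building block for fitting and as the analytic oracle for
#' the numerical integrator.
#'
#' @param y0 Initial output flux (RPU).
#' @param y_ss Steady-state target flux (RPU).
#' @param tau Relaxation rate (1/h), positive.
#' @param t Time (h), vectorized, non-negative.
#' @return Flux at time `t` (RPU).
#' @export
#' @examples
#' relax(0, 1, 1, 1)   # 1 - exp(-1)
relax <- function(y0, y_ss, tau, t) {
  stopifnot(tau > 0, all(t >= 0))
  y_ss + (y0 - y_ss) * exp(-tau * t)
}

#' Construct an inducer schedule
#'
#' A piecewise-constant schedule of sensor states: contiguous,
#' non-overlapping segments starting at time 0, each holding one input
#' bit-vector (written most-significant-input first, e.g. `"0100"` = only
#' input 3 on).
#'
#' @param start,end Segment boundaries in hours.
#' @param bits Character vector of input bit-vectors, one per segment.
#' @return An `"inducer_schedule"` tibble.
#' @export
#' @examples
#' inducer_schedule(c(0, 8), c(8, 16), c("0000", "0001"))
inducer_schedule <- function(start, end, bits) {
  df <- tibble::tibble(start = as.numeric(start), end = as.numeric(end),
                       bits = as.character(bits))
  df <- df[order(df$start), ]
  if (nrow(df) == 0) abort("Schedule error: empty schedule.")
  if (df$start[1] != 0) abort("Schedule error: first segment must start at 0.")
  if (any(df$end <= df$start))
    abort("Schedule error: each segment must have end > start.")
  if (nrow(df) > 1 && any(abs(df$start[-1] - df$end[-nrow(df)]) > 1e-9))
    abort("Schedule error: segments must be contiguous (no gaps or overlaps).")
  if (length(unique(nchar(df$bits))) != 1 || !all(grepl("^[01]+$", df$bits)))
    abort("Schedule error: bit-vectors must be 0/1 strings of equal length.")
  class(df) <- c("inducer_schedule", class(tibble::tibble()))
  df
}

#' Read / write an inducer schedule file
#'
#' Tab-separated lines `start<TAB>end<TAB>bits` (hours, hours, input
#' bit-vector written most-significant-input first).
#'
#' @param path File path.
#' @return For `read_schedule`, an `"inducer_schedule"`; `write_schedule`
#'   returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) abort(paste0("Schedule file not found: ", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start", "end", "bits"),
                          colClasses = c("numeric", "numeric", "character"))
  inducer_schedule(df$start, df$end, df$bits)
}

#' @rdname read_schedule
#' @param schedule An `"inducer_schedule"`.
#' @export
write_schedule <- function(schedule, path) {
  writeLines(paste(schedule$start, schedule$end, schedule$bits, sep = "\t"),
             path)
  invisible(path)
}

#' The digit-cycling schedule
#'
#' Eleven contiguous 8-hour segments stepping a 4-input decoder circuit
#' through the binary-coded digits 0, 1, ..., 9 and back to 0 — an 88-hour
#' protocol.
#'
#' @param segment_hours Duration of each digit segment (default 8 h).
#' @return An `"inducer_schedule"` with 11 segments.
#' @export
digit_cycle_schedule <- function(segment_hours = 8) {
  digits <- c(0:9, 0)
  starts <- (seq_along(digits) - 1) * segment_hours
  inducer_schedule(starts, starts + segment_hours,
                   state_bits_chr(digits, 4L))
}

bits_to_logical <- function(bits) {
  rev(strsplit(bits, "")[[1]] == "1")    # input 1 = last character
}

#' Simulate circuit dynamics under an inducer schedule
#'
#' Integrates the two-timescale gate model over a piecewise-constant inducer
#' schedule. Each gate node follows
#' `dy/dt = tau_on * (y_ss - y)` when `y < y_ss` and
#' `dy/dt = tau_off * (y_ss - y)` otherwise, where `y_ss` is the
#' steady-state Hill response to the node's instantaneous total input
#' (tandem-interference composition of its parents' instantaneous outputs).
#' Sensors relax toward their scheduled OFF/ON flux with their single
#' induction timescale, and the reporter integrates the output flux with
#' first-order decay. State is continuous across segment boundaries; the
#' initial condition defaults to the steady state of the first segment.
#'
#' @inheritParams evaluate_state
#' @param schedule An `"inducer_schedule"` whose bit-vectors have one bit
#'   per `INPUT` node.
#' @param y0 Optional named numeric vector of initial node fluxes (and
#'   `"reporter"`); defaults to the first segment's steady state.
#' @param options List: `rtol` (default 1e-8), `atol` (1e-10), `dt` output
#'   grid resolution in hours (default 0.1), `method` (deSolve integrator,
#'   default `"lsoda"`).
#' @return A `"circuit_trajectory"` tibble in long form: `time`, `node`,
#'   `type` (`sensor`/`gate`/`output`/`reporter`), `flux` and `flux_ss` (the
#'   instantaneous steady-state target; `NA` for output and reporter).
#' @export
simulate_circuit <- function(netlist, assignment, library, schedule,
                             model = c("interference", "additive"),
                             y0 = NULL, options = list()) {
  model <- match.arg(model)
  check_assignment_total(netlist, assignment)
  opts <- utils::modifyList(
    list(rtol = 1e-8, atol = 1e-10, dt = 0.1, method = "lsoda"), options)
  inputs <- netlist_inputs(netlist)
  if (nchar(schedule$bits[1]) != length(inputs))
    abort("Schedule bit-vectors must have one bit per circuit input.")

  gate_nodes <- netlist$node[netlist$type %in% c("NOT", "NOR2")]
  out_node <- netlist_output(netlist)
  sens_recs <- lapply(inputs, function(nm)
    lib_sensor(library, netlist$sensor[netlist$node == nm]))
  names(sens_recs) <- inputs
  gate_recs <- lapply(gate_nodes, function(nm)
    lib_gate(library, assignment$node_to_gate[[nm]]))
  names(gate_recs) <- gate_nodes
  rep_rec <- library$reporter

  # Precompute plain per-node parameter records so the ODE right-hand side
  # never touches a tibble.
  nn <- nrow(netlist)
  node_ids <- netlist$node
  par <- vector("list", nn)
  for (i in seq_len(nn)) {
    r <- netlist[i, ]
    p <- list(id = r$node, type = r$type,
              i1 = match(r$in1, node_ids), i2 = match(r$in2, node_ids))
    if (r$type == "INPUT") {
      s <- sens_recs[[r$node]]
      p <- c(p, list(input_idx = match(r$node, inputs),
                     on = s$on_rpu, off = s$off_rpu,
                     alpha = s$alpha, beta = s$beta, mode = s$mode,
                     tau_ind = s$tau_induction))
    } else if (r$type %in% c("NOT", "NOR2")) {
      g <- gate_recs[[r$node]]
      p <- c(p, list(Kn = g$K^g$n, hn = g$n, y_min = g$y_min, y_max = g$y_max,
                     alpha = g$alpha, beta = g$beta,
                     tau_on = g$tau_on, tau_off = g$tau_off))
    }
    par[[i]] <- p
  }
  additive <- model == "additive"

  # instantaneous fluxes/targets given node outputs `y` and sensor bits
  flux_pass <- function(y, bit) {
    out <- numeric(nn); occ <- numeric(nn); yss <- rep(NA_real_, nn)
    for (i in seq_len(nn)) {
      p <- par[[i]]
      if (p$type == "INPUT") {
        out[i] <- y[[p$id]]
        occ[i] <- if (additive) 1
          else if (p$mode == "activator") p$alpha
          else if (bit[p$input_idx]) p$alpha else p$alpha * p$beta
        yss[i] <- if (bit[p$input_idx]) p$on else p$off
      } else if (p$type == "OUTPUT") {
        out[i] <- if (is.na(p$i2)) out[p$i1] else
          occ[p$i2] * out[p$i1] + out[p$i2]
      } else {
        x <- if (p$type == "NOT") out[p$i1] else
          occ[p$i2] * out[p$i1] + out[p$i2]
        x <- max(x, 0)
        xn <- x^p$hn
        out[i] <- y[[p$id]]
        occ[i] <- if (additive) 1 else
          p$alpha * (p$Kn + p$beta * xn) / (p$Kn + xn)
        yss[i] <- p$y_min + (p$y_max - p$y_min) * p$Kn / (p$Kn + xn)
      }
    }
    names(out) <- node_ids
    names(yss) <- node_ids
    names(occ) <- node_ids
    list(out = out, yss = yss, occ = occ)
  }

  deriv <- function(t, y, parms) {
    bit <- parms$bit
    fp <- flux_pass(y, bit)
    dy <- numeric(length(y))
    names(dy) <- names(y)
    for (nm in inputs) {
      s <- sens_recs[[nm]]
      dy[nm] <- s$tau_induction * (fp$yss[[nm]] - y[[nm]])
    }
    for (nm in gate_nodes) {
      gt <- gate_recs[[nm]]
      target <- fp$yss[[nm]]
      tau <- if (y[[nm]] < target) gt$tau_on else gt$tau_off
      dy[nm] <- tau * (target - y[[nm]])
    }
    dy["reporter"] <- rep_rec$degradation_rate *
      (rep_rec$production_scale * fp$out[[out_node]] - y[["reporter"]])
    list(dy)
  }

  # initial condition: steady state of the first segment
  first_bit <- bits_to_logical(schedule$bits[1])
  if (is.null(y0)) {
    ss <- evaluate_states_core(
      netlist, assignment, library,
      sum(as.integer(first_bit) * 2L^(seq_along(first_bit) - 1L)), model)
    y0 <- c(
      vapply(c(inputs, gate_nodes), function(nm) ss$out[[nm]][1], numeric(1)),
      reporter = rep_rec$production_scale * ss$output[1]
    )
  } else {
    need <- c(inputs, gate_nodes, "reporter")
    if (!all(need %in% names(y0)))
      abort(paste0("`y0` must name every state: ",
                   paste(need, collapse = ", ")))
    y0 <- y0[need]
  }

  segs <- vector("list", nrow(schedule))
  state <- y0
  for (si in seq_len(nrow(schedule))) {
    t0 <- schedule$start[si]; t1 <- schedule$end[si]
    times <- unique(c(seq(t0, t1, by = opts$dt), t1))
    bit <- bits_to_logical(schedule$bits[si])
    sol <- deSolve::ode(y = state, times = times, func = deriv,
                        parms = list(bit = bit), method = opts$method,
                        rtol = opts$rtol, atol = opts$atol)
    if (any(is.na(sol)))
      abort("Numerical error: integrator returned NA values.")
    sol <- as.data.frame(sol)
    state <- unlist(sol[nrow(sol), -1])
    # drop duplicated boundary row except in the first segment
    if (si > 1) sol <- sol[-1, ]
    ssv <- lapply(seq_len(nrow(sol)), function(k) {
      yk <- unlist(sol[k, -1])
      flux_pass(yk, bit)
    })
    seg_long <- purrr::map_dfr(seq_len(nrow(sol)), function(k) {
      fp <- ssv[[k]]
      tibble::tibble(
        time = sol$time[k],
        node = c(inputs, gate_nodes, out_node, "reporter"),
        type = c(rep("sensor", length(inputs)),
                 rep("gate", length(gate_nodes)), "output", "reporter"),
        flux = unname(c(unlist(sol[k, inputs]), unlist(sol[k, gate_nodes]),
                        fp$out[[out_node]], sol[k, "reporter"])),
        flux_ss = unname(c(fp$yss[inputs], fp$yss[gate_nodes],
                           NA_real_, NA_real_)),
        occupancy = unname(c(fp$occ[inputs], fp$occ[gate_nodes],
                             NA_real_, NA_real_))
      )
    })
    segs[[si]] <- seg_long
  }
  traj <- dplyr::bind_rows(segs)
  class(traj) <- c("circuit_trajectory", class(tibble::tibble()))
  attr(traj, "netlist") <- netlist
  attr(traj, "assignment") <- assignment
  attr(traj, "schedule") <- schedule
  attr(traj, "model") <- model
  traj
}
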