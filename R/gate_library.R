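#' Construct a gate record
#'
#' A gate record holds every parameter the model needs for one repressor
#' gate: the four Hill response parameters, the two tandem-promoter
#' interference parameters of its output promoter, and the two relaxation
#' timescales.
#'
#' @param name Gate identifier, e.g. `"P1-PhlF"`.
#' @param family Repressor family, e.g. `"PhlF"`. Gates of the same family
#'   only differ in RBS/promoter variants and may not co-occur in a circuit.
#' @param y_min,y_max Minimal / maximal output promoter flux (RPU).
#' @param K Input flux at half repression (RPU).
#' @param n Hill coefficient (dimensionless).
#' @param alpha Non-specific interference factor of the output promoter when
#'   it sits downstream in a tandem pair, in (0, 1]. 1 means no suppression
#'   of the upstream promoter.
#' @param beta Roadblocking factor in (0, 1]; the residual fraction of
#'   upstream flux transmitted when the repressor is fully bound downstream.
#' @param tau_on Induction timescale (1/h): rate at which the output rises
#'   toward a higher steady state.
#' @param tau_off Relaxation timescale (1/h): rate toward a lower steady state.
#'
#' @return A one-row tibble with class information carried by the enclosing
#'   library; used as a row of `gate_library()$gates`.
#' @export
#' @examples
#' gate_record("P1-PhlF", "PhlF", 0.004, 6.9, 0.04, 3.8, 0.22, 0.06, 0.30, 4.00)
gate_record <- function(name, family, y_min, y_max, K, n,
                        alpha = 1, beta = 1, tau_on = 1, tau_off = 1) {
  tibble::tibble(
    name = as.character(name), family = as.character(family),
    y_min = as.numeric(y_min), y_max = as.numeric(y_max),
    K = as.numeric(K), n = as.numeric(n),
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    tau_on = as.numeric(tau_on), tau_off = as.numeric(tau_off)
  )
}

#' Construct a sensor record
#'
#' An inducible input system whose output promoter toggles between a
#' characterized OFF and ON flux. Sensor output promoters can themselves
#' roadblock when placed downstream in a tandem pair; since those
#' interference parameters are rarely characterized they default to 1
#' (no interference), which reproduces the purely additive composition.
#'
#' @param name Sensor identifier (the output promoter name, e.g. `"P_Tac"`).
#' @param promoter_name Output promoter name; defaults to `name`.
#' @param off_rpu,on_rpu Uninduced / induced promoter flux (RPU).
#' @param alpha,beta Interference parameters of the sensor output promoter,
#'   in (0, 1]; default 1.
#' @param tau_induction Induction/relaxation timescale of the sensor (1/h).
#' @param mode `"repressor"` (e.g. LacI, TetR: inducer clears a repressor) or
#'   `"activator"` (e.g. LuxR, CinR: inducer-bound activator recruits RNAP).
#'   Downstream occupancy differs between the two (see [roadblock_factor()]).
#'
#' @return A one-row tibble; used as a row of `gate_library()$sensors`.
#' @export
sensor_record <- function(name, promoter_name = name, off_rpu, on_rpu,
                          alpha = 1, beta = 1, tau_induction = 2,
                          mode = c("repressor", "activator")) {
  mode <- match.arg(mode)
  tibble::tibble(
    name = as.character(name), promoter_name = as.character(promoter_name),
    off_rpu = as.numeric(off_rpu), on_rpu = as.numeric(on_rpu),
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    tau_induction = as.numeric(tau_induction), mode = mode
  )
}

#' Construct a reporter record
#'
#' The reporter (YFP) integrates the circuit output flux. Its dynamics are
#' `dY/dt = degradation_rate * (production_scale * y_out - Y)`, normalized so
#' that a constant output flux `F` gives `Y -> production_scale * F`; with the
#' default `production_scale = 1` the reporter level is directly comparable
#' to the output flux in RPU.
#'
#' @param degradation_rate Effective reporter decay rate (1/h), dominated by
#'   growth dilution for a stable fluorescent protein.
#' @param production_scale Dimensionless gain between output flux and
#'   steady-state reporter level.
#' @return A list with class `"reporter_record"`.
#' @export
reporter_record <- function(degradation_rate = 0.5, production_scale = 1) {
  stopifnot(degradation_rate > 0, production_scale > 0)
  structure(
    list(degradation_rate = as.numeric(degradation_rate),
         production_scale = as.numeric(production_scale)),
    class = "reporter_record"
  )
}

#' Construct DNA layout rules
#'
#' Declarative (Eugene-style) constraints on how assigned gates are ordered
#' on the linear DNA construct and which type-IIS cloning scars separate
#' them. The scar order must begin with `"A"` and end with `"C"`: A and C
#' always flank the construct and the intermediate scars are consumed in
#' order as gates are added.
#'
#' @param gate_order Character vector: enforced forward-orientation order of
#'   repressor families.
#' @param scar_order Character vector of scar labels, first `"A"`, last `"C"`.
#' @param prohibited_pairs List of length-2 character vectors: unordered
#'   family pairs that may not co-occur in one circuit (insufficient
#'   orthogonality).
#' @param same_family_once Logical; gates sharing a repressor family may not
#'   co-occur (always `TRUE` for this gate technology).
#' @return A list with class `"layout_rules"`.
#' @export
layout_rules <- function(gate_order, scar_order, prohibited_pairs = list(),
                         same_family_once = TRUE) {
  gate_order <- as.character(gate_order)
  scar_order <- as.character(scar_order)
  if (anyDuplicated(gate_order)) abort("`gate_order` has duplicate families.")
  if (length(scar_order) < 2 || scar_order[1] != "A" ||
      scar_order[length(scar_order)] != "C") {
    abort("`scar_order` must begin with \"A\" and end with \"C\".")
  }
  structure(
    list(gate_order = gate_order, scar_order = scar_order,
         prohibited_pairs = lapply(prohibited_pairs, function(p) sort(as.character(p))),
         same_family_once = isTRUE(same_family_once)),
    class = "layout_rules"
  )
}

#' Assemble a gate library
#'
#' The library is the in-memory form of a user constraint file (UCF): the
#' characterized gates, the sensors available as circuit inputs, the reporter
#' parameters, and the DNA layout rules. All invariants are checked at
#' construction; use [validate_library()] to obtain issues as data instead.
#'
#' @param gates Tibble of gate records (rows from [gate_record()]).
#' @param sensors Tibble of sensor records (rows from [sensor_record()]).
#' @param reporter A [reporter_record()].
#' @param layout A [layout_rules()].
#' @param metadata Named list of free-form annotations (version, strain,
#'   backbone, ...). Unknown fields read from a file are preserved here.
#' @return An object of class `"gate_library"`.
#' @export
#' @examples
#' lib <- builtin_library()
#' nrow(lib$gates)
gate_library <- function(gates, sensors, reporter = reporter_record(),
                         layout, metadata = list()) {
  lib <- structure(
    list(gates = tibble::as_tibble(gates), sensors = tibble::as_tibble(sensors),
         reporter = reporter, layout = layout, metadata = metadata),
    class = "gate_library"
  )
  issues <- validate_library(lib)
  if (nrow(issues) > 0) {
    abort(c("Invalid gate library:",
            stats::setNames(paste(issues$record, issues$issue, sep = ": "),
                            rep("x", nrow(issues)))))
  }
  lib
}

#' @export
print.gate_library <- function(x, ...) {
  cat("<gate_library> ", nrow(x$gates), " gates (",
      length(unique(x$gates$family)), " families), ",
      nrow(x$sensors), " sensors\n", sep = "")
  if (length(x$metadata)) {
    keep <- intersect(c("version", "strain", "backbone"), names(x$metadata))
    for (k in keep) cat("  ", k, ": ", as.character(x$metadata[[k]]), "\n", sep = "")
  }
  invisible(x)
}

#' Validate a gate library
#'
#' Checks every record-level and library-level invariant and reports each
#' violation as one row, without raising. An empty result means the library
#' is valid.
#'
#' @param lib A `"gate_library"` (or a bare list with the same fields, so
#'   that not-yet-constructed candidates can be screened).
#' @return A tibble with columns `record` (offending record name or scope)
#'   and `issue` (human-readable rule violated).
#' @export
#' @examples
#' validate_library(builtin_library())   # zero rows
validate_library <- function(lib) {
  issues <- list()
  add <- function(record, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(record = record, issue = issue)
  }

  g <- lib$gates
  if (is.null(g) || nrow(g) == 0) {
    add("library", "gate list is empty")
  } else {
    if (anyDuplicated(g$name)) {
      for (nm in unique(g$name[duplicated(g$name)]))
        add(nm, "duplicate gate name")
    }
    for (i in seq_len(nrow(g))) {
      r <- g[i, ]
      if (!(r$y_min > 0 && r$y_min < r$y_max))
        add(r$name, "requires 0 < y_min < y_max")
      if (!(r$K > 0)) add(r$name, "requires K > 0")
      if (!(r$n > 0)) add(r$name, "requires n > 0")
      if (!(r$alpha > 0 && r$alpha <= 1))
        add(r$name, "alpha must lie in (0, 1]")
      if (!(r$beta > 0 && r$beta <= 1))
        add(r$name, "beta must lie in (0, 1]")
      if (!(r$tau_on > 0 && r$tau_off > 0))
        add(r$name, "timescales tau_on, tau_off must be positive")
    }
  }

  s <- lib$sensors
  if (!is.null(s) && nrow(s) > 0) {
    if (anyDuplicated(s$name)) {
      for (nm in unique(s$name[duplicated(s$name)]))
        add(nm, "duplicate sensor name")
    }
    for (i in seq_len(nrow(s))) {
      r <- s[i, ]
      if (!(r$off_rpu > 0 && r$off_rpu < r$on_rpu))
        add(r$name, "requires 0 < off_rpu < on_rpu")
      if (!(r$alpha > 0 && r$alpha <= 1 && r$beta > 0 && r$beta <= 1))
        add(r$name, "sensor alpha, beta must lie in (0, 1]")
      if (!(r$tau_induction > 0))
        add(r$name, "tau_induction must be positive")
      if (!r$mode %in% c("repressor", "activator"))
        add(r$name, "mode must be 'repressor' or 'activator'")
    }
  }

  if (!is.null(lib$layout) && !is.null(g) && nrow(g) > 0) {
    for (p in lib$layout$prohibited_pairs) {
      missing <- setdiff(p, lib$layout$gate_order)
      if (length(missing))
        add(paste(p, collapse = ":"),
            paste0("prohibited-pair family not in gate_order: ",
                   paste(missing, collapse = ", ")))
    }
  }

  if (length(issues) == 0) {
    tibble::tibble(record = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' The built-in characterized gate library
#'
#' Returns the packaged library: 18 repressor gates spanning 10 families with
#' fully characterized response, interference and kinetic parameters; the
#' four inducible sensors (IPTG/LacI, aTc/TetR, OC6/LuxR, OHC14/CinR) with
#' their OFF/ON fluxes; reporter defaults; and the DNA layout rules
#' (enforced family order, scar order A--B--D--E--F--X--V--U--C, and the
#' CymR:SrpR orthogonality prohibition).
#'
#' Sensor interference parameters are not characterized in this library and
#' default to `alpha = beta = 1` (flagged in `metadata$notes`), which makes
#' sensor promoters compose additively.
#'
#' @return A `"gate_library"`.
#' @export
#' @examples
#' lib <- builtin_library()
#' dplyr::filter(lib$gates, name == "P1-PhlF")
builtin_library <- function() {
  gates <- tibble::tribble(
    ~name,          ~family,   ~y_min, ~y_max, ~K,   ~n,  ~alpha, ~beta, ~tau_on, ~tau_off,
    "F1-AmeR_2",    "AmeR",    0.29,   4.6,    0.12, 1.5, 0.09,   1.00,  8.00,    2.30,
    "F2-AmeR_2",    "AmeR",    0.21,   3.7,    0.04, 1.3, 0.10,   1.00,  8.00,    2.50,
    "N1-LmrA_2",    "LmrA",    0.077,  1.3,    0.09, 1.8, 0.28,   1.00,  1.00,    1.30,
    "A1-AmtR_2",    "AmtR",    0.035,  3.1,    0.05, 1.7, 0.27,   1.00,  0.90,    2.50,
    "H1-HlyIIR_2",  "HlyIIR",  0.004,  2.1,    0.13, 2.6, 0.15,   1.00,  0.45,    4.00,
    "P1-PhlF",      "PhlF",    0.004,  6.9,    0.04, 3.8, 0.22,   0.06,  0.30,    4.00,
    "P2-PhlF",      "PhlF",    0.007,  7.5,    0.21, 4.5, 0.15,   0.12,  0.20,    4.00,
    "P3-PhlF",      "PhlF",    0.004,  7.1,    0.12, 3.3, 0.24,   0.06,  0.15,    5.00,
    "S1-SrpR",      "SrpR",    0.001,  1.4,    0.02, 3.1, 0.50,   0.05,  5.00,    7.00,
    "S2-SrpR",      "SrpR",    0.003,  3.2,    0.06, 2.7, 0.35,   0.09,  0.50,    7.00,
    "S3-SrpR",      "SrpR",    0.004,  3.1,    0.09, 2.7, 0.33,   0.10,  0.70,    6.00,
    "S4-SrpR",      "SrpR",    0.004,  3.2,    0.11, 2.7, 0.38,   0.09,  1.80,    8.00,
    "E1-BetI_2",    "BetI",    0.041,  2.8,    0.28, 2.9, 0.64,   0.46,  0.40,    1.50,
    "B1-BM3R1",     "BM3R1",   0.004,  0.6,    0.06, 2.9, 0.64,   0.05,  0.90,    1.10,
    "B2-BM3R1",     "BM3R1",   0.006,  0.5,    0.57, 3.8, 0.71,   0.05,  0.90,    1.10,
    "B3-BM3R1",     "BM3R1",   0.005,  0.6,    0.21, 3.1, 0.74,   0.05,  0.50,    2.00,
    "C1-CymR",      "CymR",    0.010,  3.0,    0.10, 3.7, 0.10,   0.07,  0.50,    2.50,
    "V1-VanR",      "VanR",    0.043,  6.2,    0.05, 2.9, 0.12,   0.32,  0.40,    11.0
  )
  sensors <- dplyr::bind_rows(
    sensor_record("P_Tac",  off_rpu = 0.008, on_rpu = 1.686, mode = "repressor"),
    sensor_record("P_Tet",  off_rpu = 0.04,  on_rpu = 1.967, mode = "repressor"),
    sensor_record("P_Lux2", off_rpu = 0.03,  on_rpu = 2.234, mode = "activator"),
    sensor_record("P_Cin",  off_rpu = 0.005, on_rpu = 3.178, mode = "activator")
  )
  layout <- layout_rules(
    gate_order = c("VanR", "PhlF", "SrpR", "AmtR", "AmeR",
                   "BM3R1", "LmrA", "HlyIIR", "BetI", "CymR"),
    scar_order = c("A", "B", "D", "E", "F", "X", "V", "U", "C"),
    prohibited_pairs = list(c("CymR", "SrpR"))
  )
  gate_library(
    gates = gates, sensors = sensors,
    reporter = reporter_record(),
    layout = layout,
    metadata = list(
      version = "builtin-1.0",
      strain = "E. coli NEB 10-beta",
      backbone = "p15a",
      notes = paste("Sensor interference parameters are uncharacterized;",
                    "alpha = beta = 1 (additive composition) is assumed.")
    )
  )
}

# Look up one gate row by name; errors on unknown names.
lib_gate <- function(library, name) {
  i <- match(name, library$gates$name)
  if (is.na(i)) abort(paste0("Unknown gate name: ", name))
  library$gates[i, ]
}

lib_sensor <- function(library, name) {
  i <- match(name, library$sensors$name)
  if (is.na(i)) abort(paste0("Unknown sensor name: ", name))
  library$sensors[i, ]
}
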