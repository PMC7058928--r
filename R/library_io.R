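# Library file I/O.
#
# The on-disk dialect is a UCF-style JSON document whose records carry their
# numeric parameters as named-parameter blocks, e.g.
#   "interference": [{"name": "alpha", "value": 0.22},
#                    {"name": "beta",  "value": 0.06}]
# When the interference block is absent for a record, alpha = beta = 1 is
# assumed and composition reverts to the purely additive model. Unknown
# fields at the top level or on individual records are preserved in
# `metadata$extra` and written back verbatim, so foreign extensions survive a
# read/modify/write cycle.

nv_block <- function(...) {
  vals <- c(...)
  unname(purrr::imap(as.list(vals), function(v, nm) list(name = nm, value = v)))
}

nv_parse <- function(block, where) {
  if (is.null(block)) return(list())
  out <- list()
  for (item in block) {
    if (is.null(item$name) || is.null(item$value))
      abort(paste0("Malformed named-parameter block in ", where,
                   ": each entry needs 'name' and 'value'."))
    out[[item$name]] <- as.numeric(item$value)
  }
  out
}

GATE_KNOWN   <- c("name", "family", "response", "interference", "kinetics")
SENSOR_KNOWN <- c("name", "promoter_name", "off_rpu", "on_rpu", "mode",
                  "interference", "kinetics")
TOP_KNOWN    <- c("format", "metadata", "gates", "sensors", "reporter", "layout")

#' Read a gate library file
#'
#' Parses the UCF-style JSON library dialect (see [write_gate_library()] for
#' the layout), validates every record invariant, and preserves any unknown
#' fields in `metadata$extra`. Records lacking an `interference` block get
#' `alpha = beta = 1`, i.e. purely additive tandem composition.
#'
#' @param path Path to a library file.
#' @return A validated `"gate_library"`.
#' @seealso [builtin_library()] for the packaged fixture, shipped at
#'   `system.file("extdata", "eco_nor_library.json", package = "norcircuit")`.
#' @export
read_gate_library <- function(path) {
  if (!file.exists(path)) abort(paste0("Library file not found: ", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("Library parse failure in '", path, "': ",
                                     conditionMessage(e)))
  )
  if (!identical(doc$format, "norcircuit-library"))
    abort(paste0("Library parse failure in '", path,
                 "': missing or unrecognized 'format' field."))

  extra <- list()
  top_extra <- doc[setdiff(names(doc), TOP_KNOWN)]
  if (length(top_extra)) extra$top <- top_extra

  parse_gate <- function(rec, i) {
    where <- paste0("gate record ", i, if (!is.null(rec$name)) paste0(" ('", rec$name, "')"))
    if (is.null(rec$name) || is.null(rec$family))
      abort(paste0("Library parse failure: ", where, " lacks 'name' or 'family'."))
    resp <- nv_parse(rec$response, where)
    need <- c("y_min", "y_max", "K", "n")
    if (!all(need %in% names(resp)))
      abort(paste0("Library parse failure: ", where, " response block lacks ",
                   paste(setdiff(need, names(resp)), collapse = ", "), "."))
    interf <- nv_parse(rec$interference, where)
    kin <- nv_parse(rec$kinetics, where)
    unknown <- rec[setdiff(names(rec), GATE_KNOWN)]
    if (length(unknown)) extra$gates[[rec$name]] <<- unknown
    gate_record(rec$name, rec$family,
                resp$y_min, resp$y_max, resp$K, resp$n,
                alpha = interf$alpha %||% 1, beta = interf$beta %||% 1,
                tau_on = kin$tau_on %||% 1, tau_off = kin$tau_off %||% 1)
  }
  parse_sensor <- function(rec, i) {
    where <- paste0("sensor record ", i)
    if (is.null(rec$name) || is.null(rec$off_rpu) || is.null(rec$on_rpu))
      abort(paste0("Library parse failure: ", where,
                   " lacks 'name', 'off_rpu' or 'on_rpu'."))
    interf <- nv_parse(rec$interference, where)
    kin <- nv_parse(rec$kinetics, where)
    unknown <- rec[setdiff(names(rec), SENSOR_KNOWN)]
    if (length(unknown)) extra$sensors[[rec$name]] <<- unknown
    sensor_record(rec$name, promoter_name = rec$promoter_name %||% rec$name,
                  off_rpu = as.numeric(rec$off_rpu), on_rpu = as.numeric(rec$on_rpu),
                  alpha = interf$alpha %||% 1, beta = interf$beta %||% 1,
                  tau_induction = kin$tau_induction %||% 2,
                  mode = rec$mode %||% "repressor")
  }

  if (is.null(doc$gates) || length(doc$gates) == 0)
    abort("Invalid gate library: gate list is empty.")
  gates <- dplyr::bind_rows(purrr::imap(doc$gates, parse_gate))
  sensors <- if (length(doc$sensors)) {
    dplyr::bind_rows(purrr::imap(doc$sensors, parse_sensor))
  } else {
    sensor_record("none", off_rpu = 1, on_rpu = 2)[0, ]
  }

  rep_rec <- if (is.null(doc$reporter)) reporter_record() else
    reporter_record(doc$reporter$degradation_rate %||% 0.5,
                    doc$reporter$production_scale %||% 1)
  lay <- doc$layout
  layout <- if (is.null(lay)) {
    layout_rules(gate_order = unique(gates$family), scar_order = c("A", "C"))
  } else {
    layout_rules(
      gate_order = unlist(lay$gate_order),
      scar_order = unlist(lay$scar_order),
      prohibited_pairs = lapply(lay$prohibited_pairs, unlist)
    )
  }
  metadata <- if (is.null(doc$metadata)) list() else doc$metadata
  if (length(extra)) metadata$extra <- extra

  gate_library(gates = gates, sensors = sensors, reporter = rep_rec,
               layout = layout, metadata = metadata)
}

#' Write a gate library file
#'
#' Serializes a library to the UCF-style JSON dialect read by
#' [read_gate_library()]. Numeric gate parameters are written as
#' named-parameter blocks (`response`, `interference`, `kinetics`); layout
#' rules and metadata are written verbatim; unknown fields previously
#' preserved in `metadata$extra` are folded back onto their records so
#' `read_gate_library(write_gate_library(lib))` is an identity.
#'
#' @param lib A `"gate_library"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gate_library <- function(lib, path) {
  stopifnot(inherits(lib, "gate_library"))
  extra <- lib$metadata$extra %||% list()
  metadata <- lib$metadata
  metadata$extra <- NULL

  gates <- purrr::pmap(lib$gates, function(name, family, y_min, y_max, K, n,
                                           alpha, beta, tau_on, tau_off) {
    rec <- list(
      name = name, family = family,
      response = nv_block(y_min = y_min, y_max = y_max, K = K, n = n),
      interference = nv_block(alpha = alpha, beta = beta),
      kinetics = nv_block(tau_on = tau_on, tau_off = tau_off)
    )
    c(rec, extra$gates[[name]])
  })
  sensors <- purrr::pmap(lib$sensors, function(name, promoter_name, off_rpu,
                                               on_rpu, alpha, beta,
                                               tau_induction, mode) {
    rec <- list(
      name = name, promoter_name = promoter_name,
      off_rpu = off_rpu, on_rpu = on_rpu, mode = mode,
      interference = nv_block(alpha = alpha, beta = beta),
      kinetics = nv_block(tau_induction = tau_induction)
    )
    c(rec, extra$sensors[[name]])
  })

  doc <- list(
    format = "norcircuit-library",
    metadata = metadata,
    gates = gates,
    sensors = sensors,
    reporter = list(degradation_rate = lib$reporter$degradation_rate,
                    production_scale = lib$reporter$production_scale),
    layout = list(gate_order = lib$layout$gate_order,
                  scar_order = lib$layout$scar_order,
                  prohibited_pairs = lib$layout$prohibited_pairs)
  )
  doc <- c(doc, extra$top)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
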