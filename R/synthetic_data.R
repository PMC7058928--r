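# Synthetic-data generators with known ground truth.
#
# These stand in for flow-cytometry medians when testing the fitters: every
# generator evaluates the forward model exactly and applies multiplicative
# lognormal noise (the conventional error model for ratio-like cytometry
# summaries), parameterized by a coefficient of variation. Zero CV returns
# the exact model values; a fixed seed reproduces the dataset bit for bit.

lognormal_factors <- function(n, cv) {
  if (cv < 0) abort("`noise_cv` must be non-negative.")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean factor = 1
}

new_synthetic_dataset <- function(data, truth, noise_cv, seed) {
  structure(tibble::as_tibble(data),
            truth = truth, noise_cv = noise_cv, seed = seed,
            class = c("synthetic_dataset", class(tibble::tibble())))
}

#' Generate a synthetic dose-response sweep
#'
#' Evaluates a gate's Hill response on a geometric grid of input fluxes
#' (default 18 points spanning the characterization range reachable with a
#' tandem sensor-promoter pair, 0.01 to 3.65 RPU) and applies multiplicative
#' lognormal noise.
#'
#' @param gate A gate record.
#' @param n_points Number of dose points (default 18).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param x_range Range of input fluxes (RPU) covered geometrically.
#' @return A `"synthetic_dataset"` tibble with columns `x`, `y`,
#'   `replicate`; the generating parameters are in `attr(, "truth")`.
#' @export
generate_sweep <- function(gate, n_points = 18, noise_cv = 0, seed = 1L,
                           x_range = c(0.01, 3.65)) {
  x <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = n_points))
  y_true <- hill_response(gate, x)
  y <- y_true * with_local_seed(seed, lognormal_factors(n_points, noise_cv))
  new_synthetic_dataset(
    tibble::tibble(x = x, y = y, replicate = 1L),
    truth = list(y_min = gate$y_min, y_max = gate$y_max, K = gate$K, n = gate$n),
    noise_cv = noise_cv, seed = seed
  )
}

#' Generate synthetic tandem-quadrant data
#'
#' Emulates the four-condition tandem-promoter experiment used to extract
#' interference parameters: an upstream sensor promoter (low/high flux) in
#' series with the output promoter of the gate under evaluation, whose own
#' input is a second sensor promoter (low/high flux). The observed output is
#' the interference-corrected upstream flux plus the gate's Hill response.
#'
#' @param gate Downstream gate record (its `K`, `n` govern occupancy).
#' @param alpha,beta True interference parameters used to generate the data;
#'   default to the gate record's values.
#' @param upstream_levels Upstream sensor promoter flux, `c(low, high)` RPU.
#' @param input_levels Gate-input sensor promoter flux, `c(low, high)` RPU.
#' @param n_replicates Independent replicate measurements averaged per
#'   condition (default 3, mirroring the triplicate experimental protocol;
#'   the reported `y` is the replicate mean).
#' @inheritParams generate_sweep
#' @return A `"synthetic_dataset"` with four rows: `upstream_on`,
#'   `input_on`, `x_up`, `x_in`, `y`.
#' @export
generate_quadrants <- function(gate, alpha = gate$alpha, beta = gate$beta,
                               upstream_levels = c(0.04, 1.967),
                               input_levels = c(0.008, 1.686),
                               noise_cv = 0, seed = 1L, n_replicates = 3) {
  grid <- expand.grid(upstream_on = c(FALSE, TRUE), input_on = c(FALSE, TRUE))
  x_up <- ifelse(grid$upstream_on, upstream_levels[2], upstream_levels[1])
  x_in <- ifelse(grid$input_on, input_levels[2], input_levels[1])
  mod <- gate
  mod$alpha <- alpha
  mod$beta <- beta
  y_true <- roadblock_factor(mod, x_in) * x_up + hill_response(gate, x_in)
  factors <- with_local_seed(seed, matrix(
    lognormal_factors(4 * n_replicates, noise_cv), nrow = 4))
  y <- y_true * rowMeans(factors)
  new_synthetic_dataset(
    tibble::tibble(upstream_on = grid$upstream_on, input_on = grid$input_on,
                   x_up = x_up, x_in = x_in, y = y),
    truth = list(alpha = alpha, beta = beta),
    noise_cv = noise_cv, seed = seed
  )
}

# Deterministic forward simulation of the gate-switching chain: a sensor
# relaxes toward its new level, the gate follows its two-timescale ODE
# toward the instantaneous Hill response, and the reporter integrates the
# gate output. Returns reporter values on `times`.
simulate_switch_chain <- function(gate, direction, times,
                                  x_low = 0.048, x_high = 3.653,
                                  sensor_tau = 2,
                                  reporter = reporter_record()) {
  from_x <- if (direction == "on_to_off") x_low else x_high
  to_x <- if (direction == "on_to_off") x_high else x_low
  y0g <- hill_response(gate, from_x)
  state <- c(s = from_x, y = y0g, Y = reporter$production_scale * y0g)
  deriv <- function(t, y, parms) {
    yss <- hill_response(gate, y[["s"]])
    tau <- if (y[["y"]] < yss) gate$tau_on else gate$tau_off
    list(c(
      s = sensor_tau * (to_x - y[["s"]]),
      y = tau * (yss - y[["y"]]),
      Y = reporter$degradation_rate *
        (reporter$production_scale * y[["y"]] - y[["Y"]])
    ))
  }
  sol <- deSolve::ode(y = state, times = unique(c(0, times)), func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  sol <- as.data.frame(sol)
  sol$Y[match(times, sol$time)]
}

#' Generate a synthetic switching time course
#'
#' Simulates the full measurement chain for a gate-switching experiment
#' (sensor induction, two-timescale gate relaxation, reporter integration)
#' and applies multiplicative lognormal noise to the reporter readout.
#' Direction `"on_to_off"` starts the gate fully ON (inputs low) and turns
#' the inputs on at `t = 0`; `"off_to_on"` is the reverse protocol.
#'
#' @param gate Gate record providing the true timescales.
#' @param direction `"on_to_off"` or `"off_to_on"`.
#' @param grid Sampling times in hours.
#' @inheritParams generate_sweep
#' @param x_low,x_high Combined input promoter flux before/after switching
#'   (RPU); defaults to the OFF and ON flux of a tandem sensor pair.
#' @param sensor_tau Sensor induction timescale (1/h).
#' @param reporter A [reporter_record()].
#' @return A `"synthetic_dataset"` with columns `time`, `y`, `replicate`.
#' @export
generate_timecourse <- function(gate, direction = c("on_to_off", "off_to_on"),
                                grid = seq(0, 12, by = 0.5), noise_cv = 0,
                                seed = 1L, x_low = 0.048, x_high = 3.653,
                                sensor_tau = 2, reporter = reporter_record()) {
  direction <- match.arg(direction)
  y_true <- simulate_switch_chain(gate, direction, grid,
                                  x_low = x_low, x_high = x_high,
                                  sensor_tau = sensor_tau, reporter = reporter)
  y <- y_true * with_local_seed(seed, lognormal_factors(length(grid), noise_cv))
  truth <- list(tau = if (direction == "on_to_off") gate$tau_off else gate$tau_on,
                direction = direction)
  new_synthetic_dataset(
    tibble::tibble(time = grid, y = y, replicate = 1L),
    truth = truth, noise_cv = noise_cv, seed = seed
  )
}
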