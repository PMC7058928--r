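# Parameter fitting from dose-response, tandem-quadrant and time-course data.

new_circuit_fit <- function(type, estimates, residual_norm, converged,
                            constraint_active = NULL, n_obs = NA_integer_,
                            message = NULL) {
  structure(
    list(type = type, estimates = estimates, residual_norm = residual_norm,
         converged = converged,
         constraint_active = constraint_active %||%
           stats::setNames(rep(FALSE, length(estimates)), names(estimates)),
         n_obs = n_obs, message = message),
    class = "circuit_fit"
  )
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat("<circuit_fit:", x$type, ">",
      if (!x$converged) " (not converged)", "\n", sep = "")
  for (nm in names(x$estimates)) {
    cat("  ", nm, " = ", format(x$estimates[[nm]], digits = 6),
        if (isTRUE(x$constraint_active[[nm]])) "  [at constraint]", "\n",
        sep = "")
  }
  cat("  residual norm: ", format(x$residual_norm, digits = 4),
      "  (n = ", x$n_obs, ")\n", sep = "")
  invisible(x)
}

#' Fit a Hill response function to dose-response data
#'
#' Nonlinear least squares on log-output residuals (appropriate because
#' promoter activities span orders of magnitude and cytometry-derived RPU
#' errors are multiplicative). Fitting uses bounded Levenberg-Marquardt with
#' seeded random multi-starts to avoid local minima in the Hill coefficient.
#'
#' @param points A data frame with columns `x` (input RPU, >= 0) and `y`
#'   (output RPU, > 0); at least 5 points spanning the response.
#' @param bounds Named list overriding the default box constraints
#'   `lower = c(y_min = 1e-6, y_max = 1e-6, K = 1e-6, n = 0.5)`,
#'   `upper = c(y_min = Inf, y_max = Inf, K = Inf, n = 8)`.
#' @param n_starts Number of random multi-starts (default 10).
#' @param seed Seed for the multi-start perturbations.
#' @return A `"circuit_fit"` with estimates `y_min`, `y_max`, `K`, `n`.
#'   A flat response is flagged as non-identifiable (`converged = FALSE`)
#'   rather than raising.
#' @export
#' @examples
#' lib <- builtin_library()
#' phlf <- dplyr::filter(lib$gates, name == "P2-PhlF")
#' sweep <- generate_sweep(phlf, noise_cv = 0)
#' fit_hill(sweep)$estimates
fit_hill <- function(points, bounds = list(), n_starts = 10, seed = 1L) {
  if (nrow(points) < 5)
    abort("Hill fitting needs at least 5 dose-response points.")
  if (any(points$x < 0) || any(points$y <= 0))
    abort("Dose-response data require x >= 0 and y > 0.")
  lower <- c(y_min = 1e-6, y_max = 1e-6, K = 1e-6, n = 0.5)
  upper <- c(y_min = Inf, y_max = Inf, K = Inf, n = 8)
  if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
  if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper

  logy <- log(points$y)
  if (stats::sd(logy) < 1e-10) {
    est <- c(y_min = min(points$y), y_max = max(points$y) * (1 + 1e-6),
             K = stats::median(points$x), n = 1)
    return(new_circuit_fit("hill", est, residual_norm = 0, converged = FALSE,
                           n_obs = nrow(points),
                           message = "constant response: parameters not identifiable"))
  }

  base_start <- c(
    y_min = max(min(points$y) * 0.9, lower[["y_min"]] * 2),
    y_max = max(points$y) * 1.05,
    K = exp(mean(log(pmax(points$x, 1e-4)))),
    n = 2
  )
  starts <- with_local_seed(seed, {
    c(list(base_start), lapply(seq_len(max(n_starts - 1, 0)), function(i) {
      s <- base_start * exp(stats::rnorm(4, 0, 0.5))
      s["n"] <- min(max(s[["n"]], lower[["n"]]), upper[["n"]])
      s
    }))
  })

  objective <- function(p) {
    pred <- p[["y_min"]] + (p[["y_max"]] - p[["y_min"]]) *
      p[["K"]]^p[["n"]] / (p[["K"]]^p[["n"]] + points$x^p[["n"]])
    if (any(pred <= 0)) return(rep(1e6, nrow(points)))
    log(pred) - logy
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lower), upper), fn = objective,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    return(new_circuit_fit("hill",
                           stats::setNames(rep(NA_real_, 4),
                                           c("y_min", "y_max", "K", "n")),
                           residual_norm = NA_real_, converged = FALSE,
                           n_obs = nrow(points),
                           message = "optimizer failed from every start"))
  }
  est <- stats::coef(best$fit)
  active <- abs(est - lower) < 1e-8 | abs(est - upper) < 1e-8
  new_circuit_fit("hill", est, residual_norm = best$rn,
                  converged = best$fit$info %in% 1:4 && est[["y_max"]] > est[["y_min"]],
                  constraint_active = active, n_obs = nrow(points))
}

#' Fit tandem-promoter interference parameters
#'
#' Extracts `alpha` (non-specific suppression) and `beta` (roadblocking)
#' from the four-condition tandem experiment: observed output =
#' `alpha * (K^n + beta * x_in^n) / (K^n + x_in^n) * x_up +
#' hill_response(gate, x_in)`. The model is linear in `(alpha,
#' alpha * beta)`, so the unconstrained least-squares solution (linear
#' space; with only four points a variance-stabilizing transform has
#' nothing to gain) is computed first and projected onto the admissible box
#' `alpha, beta` in (0, 1] by bounded refinement when it falls outside.
#'
#' @param quadrants Data frame with columns `x_up`, `x_in`, `y` (four rows,
#'   one per low/high combination), e.g. from [generate_quadrants()].
#' @param gate The downstream gate record (provides `K`, `n` and the
#'   response function); its stored `alpha`/`beta` are ignored.
#' @return A `"circuit_fit"` with estimates `alpha`, `beta`; estimates at
#'   the upper bound 1 (additive behavior) are flagged `constraint_active`.
#' @export
fit_interference <- function(quadrants, gate) {
  need <- c("x_up", "x_in", "y")
  if (!all(need %in% names(quadrants)) || nrow(quadrants) < 4)
    abort("Quadrant data require four rows with columns x_up, x_in, y.")
  Kn <- gate$K^gate$n
  xn <- quadrants$x_in^gate$n
  # response = a * basis1 + b * basis2 + hill,  a = alpha, b = alpha * beta
  basis1 <- Kn / (Kn + xn) * quadrants$x_up
  basis2 <- xn / (Kn + xn) * quadrants$x_up
  resp <- quadrants$y - hill_response(gate, quadrants$x_in)

  ab <- tryCatch(stats::coef(stats::lm.fit(cbind(basis1, basis2), resp)),
                 error = function(e) c(NA_real_, NA_real_))
  eps <- 1e-9
  feasible_ls <- all(is.finite(ab)) && ab[1] > 0 && ab[1] <= 1 &&
    ab[2] > 0 && ab[2] <= ab[1]
  if (feasible_ls) {
    est <- c(alpha = min(unname(ab[1]), 1),
             beta = min(unname(ab[2] / ab[1]), 1))
  } else {
    obj <- function(p) {
      sum((p[1] * basis1 + p[1] * p[2] * basis2 - resp)^2)
    }
    opt <- stats::optim(c(alpha = 0.5, beta = 0.5), obj, method = "L-BFGS-B",
                        lower = c(eps, eps), upper = c(1, 1),
                        control = list(factr = 1e4))
    est <- c(alpha = unname(opt$par[1]), beta = unname(opt$par[2]))
  }
  pred <- est[["alpha"]] * basis1 + est[["alpha"]] * est[["beta"]] * basis2
  rn <- sqrt(sum((pred - resp)^2))
  active <- c(alpha = est[["alpha"]] > 1 - 1e-6, beta = est[["beta"]] > 1 - 1e-6)
  new_circuit_fit("interference", est, residual_norm = rn, converged = TRUE,
                  constraint_active = active, n_obs = nrow(quadrants))
}

#' Fit a gate switching timescale from a time course
#'
#' Fits the relevant relaxation rate (`tau_off` for an ON-to-OFF
#' experiment, `tau_on` for OFF-to-ON) by least squares between the
#' observed time course and the full measurement chain (sensor induction,
#' gate relaxation, reporter integration), both normalized by their value
#' at `t = 0`. Normalization makes the fit invariant to the absolute
#' reporter scale.
#'
#' @param timecourse Data frame with columns `time` (h) and `y` (reporter
#'   readout); at least 4 points including `t = 0`.
#' @param direction `"on_to_off"` or `"off_to_on"`.
#' @param gate Gate record supplying the response function (its stored
#'   timescales are ignored).
#' @param x_low,x_high,sensor_tau,reporter Measurement-chain context; see
#'   [generate_timecourse()].
#' @param tau_range Search interval for the timescale (1/h).
#' @return A `"circuit_fit"` with estimate `tau`; a flat time course is
#'   flagged non-identifiable.
#' @export
fit_timescales <- function(timecourse, direction = c("on_to_off", "off_to_on"),
                           gate, x_low = 0.048, x_high = 3.653,
                           sensor_tau = 2, reporter = reporter_record(),
                           tau_range = c(0.01, 30)) {
  direction <- match.arg(direction)
  if (nrow(timecourse) < 4)
    abort("Timescale fitting needs at least 4 time points.")
  obs <- timecourse$y / timecourse$y[which.min(timecourse$time)]
  if (stats::sd(obs) < 1e-10) {
    return(new_circuit_fit("timescale", c(tau = NA_real_),
                           residual_norm = 0, converged = FALSE,
                           n_obs = nrow(timecourse),
                           message = "flat time course: tau not identifiable"))
  }
  times <- timecourse$time
  obj <- function(tau) {
    g <- gate
    if (direction == "on_to_off") g$tau_off <- tau else g$tau_on <- tau
    pred <- simulate_switch_chain(g, direction, times, x_low = x_low,
                                  x_high = x_high, sensor_tau = sensor_tau,
                                  reporter = reporter)
    pred <- pred / pred[which.min(times)]
    sum((pred - obs)^2)
  }
  opt <- stats::optimize(obj, interval = tau_range, tol = 1e-8)
  new_circuit_fit("timescale", c(tau = opt$minimum),
                  residual_norm = sqrt(opt$objective), converged = TRUE,
                  n_obs = nrow(timecourse))
}
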