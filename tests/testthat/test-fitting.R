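lib <- builtin_library()
p1 <- dplyr::filter(lib$gates, name == "P1-PhlF")
p2 <- dplyr::filter(lib$gates, name == "P2-PhlF")

test_that("synthetic generators are exact at zero noise and seed-reproducible", {
  sw <- generate_sweep(p2, noise_cv = 0)
  expect_equal(nrow(sw), 18)
  expect_equal(sw$y, hill_response(p2, sw$x))

  sw1 <- generate_sweep(p2, noise_cv = 0.1, seed = 7)
  sw2 <- generate_sweep(p2, noise_cv = 0.1, seed = 7)
  expect_identical(sw1$y, sw2$y)
  expect_false(identical(sw1$y, generate_sweep(p2, noise_cv = 0.1, seed = 8)$y))

  q1 <- generate_quadrants(p1, noise_cv = 0.05, seed = 3)
  expect_equal(nrow(q1), 4)
  expect_identical(q1$y, generate_quadrants(p1, noise_cv = 0.05, seed = 3)$y)

  tc <- generate_timecourse(p1, "on_to_off", noise_cv = 0, seed = 1)
  expect_identical(tc$y, generate_timecourse(p1, "on_to_off", seed = 2)$y)
  expect_equal(attr(tc, "truth")$tau, p1$tau_off)
})

test_that("fit_hill recovers generating parameters from noise-free sweeps", {
  for (g in list(p1, p2)) {
    fit <- fit_hill(generate_sweep(g, noise_cv = 0))
    expect_true(fit$converged)
    est <- fit$estimates
    truth <- c(y_min = g$y_min, y_max = g$y_max, K = g$K, n = g$n)
    expect_equal(est[names(truth)], truth, tolerance = 0.01)
  }
})

test_that("fit_hill is equivariant under point reordering", {
  sw <- generate_sweep(p2, noise_cv = 0.05, seed = 5)
  f1 <- fit_hill(sw)
  f2 <- fit_hill(sw[rev(seq_len(nrow(sw))), ])
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("fit_hill flags degenerate data instead of raising", {
  flat <- tibble::tibble(x = 1:6, y = rep(2, 6), replicate = 1L)
  fit <- fit_hill(flat)
  expect_false(fit$converged)
  expect_error(fit_hill(tibble::tibble(x = 1:3, y = 1:3)), "at least 5")
  expect_error(fit_hill(tibble::tibble(x = c(-1, 1:5), y = rep(1, 6))), "x >= 0")
})

test_that("fit_hill K error stays small under multiplicative noise", {
  errs <- vapply(1:50, function(s) {
    fit <- fit_hill(generate_sweep(p2, noise_cv = 0.05, seed = s),
                    n_starts = 4)
    abs(fit$estimates[["K"]] - p2$K) / p2$K
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})

test_that("fit_interference recovers alpha and beta exactly at zero noise", {
  q <- generate_quadrants(p1, noise_cv = 0)
  fit <- fit_interference(q, p1)
  expect_equal(fit$estimates[["alpha"]], 0.22, tolerance = 1e-6)
  expect_equal(fit$estimates[["beta"]], 0.06, tolerance = 1e-6)
  expect_false(any(fit$constraint_active))
})

test_that("additively generated quadrants pin the estimates at the bound", {
  q <- generate_quadrants(p1, alpha = 1, beta = 1, noise_cv = 0)
  fit <- fit_interference(q, p1)
  expect_equal(fit$estimates[["alpha"]], 1, tolerance = 1e-6)
  expect_equal(fit$estimates[["beta"]], 1, tolerance = 1e-6)
  expect_true(all(fit$constraint_active))
})

test_that("fitted interference parameters never exceed one", {
  set.seed(9)
  for (i in 1:20) {
    q <- generate_quadrants(p1, alpha = stats::runif(1, 0.1, 1),
                            beta = stats::runif(1, 0.05, 1),
                            noise_cv = 0.3, seed = i)
    fit <- fit_interference(q, p1)
    expect_lte(fit$estimates[["alpha"]], 1)
    expect_lte(fit$estimates[["beta"]], 1)
    expect_gt(fit$estimates[["alpha"]], 0)
    expect_gt(fit$estimates[["beta"]], 0)
  }
})

test_that("alpha is recovered within 0.1 median error at 5% noise", {
  errs <- vapply(1:50, function(s) {
    fit <- fit_interference(generate_quadrants(p1, noise_cv = 0.05, seed = s),
                            p1)
    abs(fit$estimates[["alpha"]] - p1$alpha)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)
})

test_that("fit_timescales recovers both switching timescales at zero noise", {
  tc_off <- generate_timecourse(p1, "on_to_off", noise_cv = 0)
  fit_off <- fit_timescales(tc_off, "on_to_off", p1)
  expect_equal(fit_off$estimates[["tau"]], p1$tau_off, tolerance = 0.01)

  tc_on <- generate_timecourse(p1, "off_to_on", noise_cv = 0)
  fit_on <- fit_timescales(tc_on, "off_to_on", p1)
  expect_equal(fit_on$estimates[["tau"]], p1$tau_on, tolerance = 0.01)
})

test_that("normalization makes the timescale fit scale-invariant", {
  tc <- generate_timecourse(p1, "on_to_off", noise_cv = 0.05, seed = 4)
  f1 <- fit_timescales(tc, "on_to_off", p1)
  scaled <- tc
  scaled$y <- scaled$y * 37.5
  f2 <- fit_timescales(scaled, "on_to_off", p1)
  expect_equal(f1$estimates[["tau"]], f2$estimates[["tau"]], tolerance = 1e-8)
})

test_that("flat or too-short time courses are flagged", {
  flat <- tibble::tibble(time = 0:5, y = rep(1, 6))
  expect_false(fit_timescales(flat, "on_to_off", p1)$converged)
  expect_error(fit_timescales(tibble::tibble(time = 0:2, y = 1:3),
                              "on_to_off", p1), "at least 4")
})

test_that("tidy and glance expose fit results as tibbles", {
  fit <- fit_hill(generate_sweep(p2, noise_cv = 0))
  td <- tidy(fit)
  expect_identical(td$term, c("y_min", "y_max", "K", "n"))
  expect_type(td$estimate, "double")
  gl <- glance(fit)
  expect_identical(gl$fit_type, "hill")
  expect_true(gl$converged)
  expect_equal(gl$n_obs, 18)
})
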