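test_that("steady-state detection returns the settled tail mean", {
  t <- (0:499) * 2
  const <- temp_trace(tibble::tibble(time_s = t, T0 = 31.2))
  expect_equal(detect_steady_state(const, "T0"), 31.2)

  settled <- make_first_order_trace(2.8, T_ss = 34, duration_s = 10 * 2.8 * 60)
  expect_lt(abs(detect_steady_state(settled, "T0") - 34), 1e-3)

  rising <- make_first_order_trace(2.8, T_ss = 34, duration_s = 2.8 * 60)
  expect_error(detect_steady_state(rising, "T0"),
               class = "prosthermal_not_steady_error")
  expect_error(detect_steady_state(settled, "nope"),
               class = "prosthermal_format_error")
})

test_that("log-linearisation is exactly linear for ideal first-order data", {
  tr <- make_first_order_trace(2.0, T_init = 22, T_ss = 34)
  ld <- log_linearize(tr, "T0", steady_state_c = 34)
  fit <- lm(log_delta ~ time_s, data = ld)
  expect_equal(summary(fit)$r.squared, 1, tolerance = 1e-12)
  # slope of ln(T_ss - T) is -1/tau: tau = 2 min -> -1/120 per second
  expect_equal(unname(coef(fit)[2]), -1 / 120, tolerance = 1e-12)
})

test_that("log-linearisation excludes samples at or above the steady state", {
  t <- (0:99) * 2
  y <- c(rep(30, 50), rep(34.5, 50))   # second half above the steady state
  tr <- temp_trace(tibble::tibble(time_s = t, T0 = y))
  ld <- log_linearize(tr, "T0", steady_state_c = 34)
  expect_equal(nrow(ld), 50)
  expect_true(all(ld$time_s < 100))

  flat <- temp_trace(tibble::tibble(time_s = t, T0 = rep(33.95, 100)))
  expect_error(log_linearize(flat, "T0", steady_state_c = 34),
               class = "prosthermal_insufficient_data_error")
})

test_that("logarithmic method recovers tau exactly on noiseless data", {
  for (tau in c(0.6, 1.6, 2.6, 2.8, 3.1, 3.6, 4.0, 4.1, 4.5)) {
    tr <- make_first_order_trace(tau, T_init = 22, T_ss = 32.2)
    est <- estimate_tau(tr, "T0", steady_state_c = 32.2, check_steady = FALSE)
    expect_lt(abs(est$tau_min - tau), 1e-6)
    expect_equal(est$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("steady-state refinement matches the known-asymptote fit on truncated records", {
  # 30 min record of a tau = 6.7 min response: only ~4.5 tau observed
  st <- pelite_thermo()
  tr <- suppressWarnings(
    simulate_stack(st, 34, 22, duration_s = 1800, noise_sd_c = 0))
  est <- estimate_tau(tr, "T2")
  expect_lt(abs(est$tau_min - 6.7), 1e-5)
  expect_lt(abs(est$steady_state_c - trace_meta(tr)$steady_state_c), 1e-4)
})

test_that("noisy estimates agree with a direct nonlinear least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  st <- pelite_thermo()
  tr <- suppressWarnings(
    simulate_stack(st, 34, 22, duration_s = 1800, noise_sd_c = 0.05, seed = 1))
  est <- estimate_tau(tr, "T2")
  d <- data.frame(t = tr$time_s, y = tr$T2)
  nls_fit <- minpack.lm::nlsLM(y ~ Tss + (22 - Tss) * exp(-t / (60 * tau)),
                               data = d, start = list(Tss = 32, tau = 5))
  tau_oracle <- unname(coef(nls_fit)["tau"])
  expect_lt(abs(est$tau_min - tau_oracle), 0.2)
  expect_lt(abs(est$tau_min - tau_oracle) / tau_oracle, 0.05)
})

test_that("estimator bias shrinks as sensor noise goes to zero", {
  biases <- vapply(c(0.2, 0.1, 0.05, 0.01), function(sdn) {
    taus <- vapply(1:50, function(s) {
      tr <- simulate_single_layer(technogel(), 34, 22, duration_s = 1800,
                                  noise_sd_c = sdn, seed = s)
      estimate_tau(tr, "T0", slope_tol_c_per_min = 0.5)$tau_min
    }, numeric(1))
    abs(mean(taus) - 2.8)
  }, numeric(1))
  expect_true(all(diff(biases) < 0))
})

test_that("non-decaying data raises an estimation error", {
  t <- (0:99) * 2
  cooling <- temp_trace(tibble::tibble(time_s = t, T0 = 30 - 0.02 * t))
  expect_error(
    estimate_tau(cooling, "T0", steady_state_c = 31, check_steady = FALSE),
    class = "prosthermal_estimation_error")
})

test_that("set-point aggregation averages and flags dispersion", {
  agg <- aggregate_tau(data.frame(setpoint_c = c(30, 32), tau_min = c(2.7, 2.9)))
  expect_equal(agg$tau_mean_min, 2.8)
  expect_equal(agg$dispersion_min, sd(c(2.7, 2.9)), tolerance = 1e-12)

  # noiseless set-point sweep: dispersion at numerical zero
  ests <- lapply(seq(30, 40, 2), function(sp) {
    tr <- simulate_single_layer(technogel(), sp, 22, duration_s = 1800,
                                noise_sd_c = 0)
    estimate_tau(tr, "T0", steady_state_c = trace_meta(tr)$steady_state_c)
  })
  agg2 <- aggregate_tau(setNames(ests, seq(30, 40, 2)))
  expect_equal(agg2$tau_mean_min, 2.8, tolerance = 1e-9)
  expect_lt(agg2$dispersion_min, 1e-9)

  expect_warning(
    aggregate_tau(data.frame(setpoint_c = c(30, 32), tau_min = c(2.0, 3.0))),
    "dispersion")
  expect_error(aggregate_tau(data.frame(setpoint_c = 30, tau_min = 2.8)),
               class = "prosthermal_validation_error")
  expect_error(aggregate_tau(list()), class = "prosthermal_validation_error")
})

test_that("tau_fit supports broom-style accessors", {
  tr <- make_first_order_trace(2.8)
  est <- estimate_tau(tr, "T0")
  td <- tidy(est)
  expect_setequal(td$term, c("tau_min", "slope_per_s", "intercept"))
  expect_equal(td$estimate[td$term == "tau_min"], est$tau_min)
  gl <- glance(est)
  expect_equal(gl$tau_min, est$tau_min)
  expect_gte(gl$n_points_used, 3)
  expect_s3_class(autoplot(est), "ggplot")
})
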