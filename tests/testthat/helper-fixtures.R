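# Shared fixtures: all synthetic, built in code at test time.

# ideal first-order heating curve as a temp_trace
make_first_order_trace <- function(tau_min, T_init = 22, T_ss = 34,
                                   duration_s = 1800, rate_hz = 0.5) {
  t <- (seq_len(floor(duration_s * rate_hz)) - 1) / rate_hz
  temp_trace(tibble::tibble(
    time_s = t,
    T0 = first_order_response(t, T_init, T_ss, tau_min)))
}

technogel <- function() get_material("OttoBock Technogel")

tech_thermoset <- function() get_stack("OttoBock Technogel", "thermosetting lay-up")

pelite_thermo <- function() get_stack("Pe-lite", "thermoplastic")

# smooth nonlinear target for GP parameter-recovery checks
smooth_fn <- function(x) 32 + 1.2 * sin(x / 2) + 0.3 * x

# lagged Pearson correlation between two series; positive lag means
# `follower` trails `leader`
best_lag <- function(leader, follower, max_lag = 150) {
  n <- length(leader)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(leader[1:(n - k)], follower[(1 + k):n])
    else stats::cor(leader[(1 - k):n], follower[1:(n + k)])
  }, numeric(1))
  lags[which.max(r)]
}
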