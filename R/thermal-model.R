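#' First-order thermal step response
#'
#' Lumped-capacitance response of a material layer to a constant heat
#' source: the difference from the steady state decays exponentially,
#' `T(t) = T_ss + (T_init - T_ss) * exp(-t / tau)`. The time constant
#' `tau` is the time to traverse 63.2% (1 - 1/e) of the full step.
#'
#' @param time_s Vector of times in seconds (>= 0).
#' @param T_init Initial temperature, degrees C.
#' @param T_ss Steady-state (asymptotic) temperature, degrees C.
#' @param tau_min Thermal time constant in minutes (> 0).
#' @return Temperature vector, degrees C, same length as `time_s`.
#' @export
#' @examples
#' first_order_response(c(0, 2.8 * 60), T_init = 22, T_ss = 34, tau_min = 2.8)
first_order_response <- function(time_s, T_init, T_ss, tau_min) {
  if (!is.numeric(tau_min) || length(tau_min) != 1 || !is.finite(tau_min) ||
      tau_min <= 0) {
    abort("`tau_min` must be a single positive number",
          class = "prosthermal_validation_error")
  }
  if (any(time_s < 0)) {
    abort("times must be non-negative", class = "prosthermal_validation_error")
  }
  T_ss + (T_init - T_ss) * exp(-time_s / (60 * tau_min))
}

# Response of a first-order node with time constant tau_min driven by a
# target g0 + g1 * exp(-t / tau_drive_min), starting at L0. Closed form;
# the equal-time-constant case uses the resonant t*exp(-t/tau) solution.
first_order_node <- function(time_s, L0, g0, g1, tau_min, tau_drive_min) {
  tau_s <- 60 * tau_min
  taud_s <- 60 * tau_drive_min
  if (abs(taud_s - tau_s) < 1e-9 * tau_s) {
    g0 + (L0 - g0) * exp(-time_s / tau_s) +
      g1 * (time_s / tau_s) * exp(-time_s / tau_s)
  } else {
    cc <- g1 * taud_s / (taud_s - tau_s)
    g0 + (L0 - g0 - cc) * exp(-time_s / tau_s) + cc * exp(-time_s / taud_s)
  }
}

sim_time_grid <- function(duration_s, sample_rate_hz) {
  n <- floor(duration_s * sample_rate_hz)
  if (n < 2) {
    abort("duration too short for the requested sample rate",
          class = "prosthermal_validation_error")
  }
  (seq_len(n) - 1) / sample_rate_hz
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a bench test of a single prosthetic layer
#'
#' Emulates the heating-tape bench experiment: a layer at ambient
#' temperature is placed on a heat source held at `setpoint_c`, and the
#' outer-surface temperature `T0` rises as a first-order response. The
#' observed steady state sits below the set-point because heat is lost from
#' the free surface; the shortfall is modelled as `loss_coef` times the
#' set-point-to-ambient difference. `T1` is the (noiseless) source channel;
#' i.i.d. Gaussian sensor noise is added to `T0`.
#'
#' @param material One-row material tibble ([get_material()]).
#' @param setpoint_c Heat-source set-point, degrees C (> ambient).
#' @param ambient_c Ambient (and initial layer) temperature, degrees C.
#' @param duration_s Recording length, seconds. A warning (and a
#'   `short_duration` metadata flag) is raised when it covers less than
#'   5 time constants.
#' @param sample_rate_hz Logger sampling rate, Hz.
#' @param noise_sd_c Sensor noise standard deviation, degrees C.
#' @param seed Optional integer seed; the same seed reproduces the trace
#'   exactly.
#' @param loss_coef Fraction of `setpoint_c - ambient_c` lost at steady
#'   state, so `T_ss = setpoint_c - loss_coef * (setpoint_c - ambient_c)`.
#' @return A [temp_trace()] with channels `T1`, `T0`; metadata records the
#'   set-point, ambient, true steady state and seed.
#' @export
simulate_single_layer <- function(material, setpoint_c, ambient_c = 22,
                                  duration_s = 1800, sample_rate_hz = 0.5,
                                  noise_sd_c = 0.05, seed = NULL,
                                  loss_coef = 0.15) {
  if (setpoint_c <= ambient_c) {
    abort("setpoint_c must exceed ambient_c", class = "prosthermal_validation_error")
  }
  tau <- material$tau_min
  t <- sim_time_grid(duration_s, sample_rate_hz)
  short <- duration_s < 5 * 60 * tau
  if (short) {
    warn(sprintf("duration %.0f s covers only %.1f time constants (< 5)",
                 duration_s, duration_s / (60 * tau)))
  }
  T_ss <- setpoint_c - loss_coef * (setpoint_c - ambient_c)
  T0 <- first_order_response(t, T_init = ambient_c, T_ss = T_ss, tau_min = tau)
  noise <- with_seed(seed, rnorm(length(t), 0, noise_sd_c))
  temp_trace(
    tibble::tibble(time_s = t, T1 = setpoint_c, T0 = T0 + noise),
    sample_rate_hz = sample_rate_hz,
    meta = list(material = material$name, tau_min = tau,
                setpoint_c = setpoint_c, ambient_c = ambient_c,
                steady_state_c = T_ss, noise_sd_c = noise_sd_c, seed = seed,
                short_duration = short))
}

#' Simulate a bench test of a stacked liner + socket pair
#'
#' Emulates the two-layer bench experiment: the liner sits on the heating
#' tape with the socket shell on top. `T1` is the source, `T2` the liner
#' interface (outer liner surface) and `T3` the outer socket surface. `T2`
#' follows a first-order response whose time constant is the measured
#' combination value `stack$combo_tau_min`; `T3` is a second first-order
#' node (time constant = the socket's individual tau) chasing an attenuated
#' copy of `T2`, so `T3 <= T2 <= T1` at all times and the outer surface lags.
#'
#' @inheritParams simulate_single_layer
#' @param stack A [stack_spec()] with `combo_tau_min` present.
#' @param loss_coef,outer_loss_coef Steady-state loss fractions at the liner
#'   interface and outer socket surface (the outer surface loses more).
#' @return A [temp_trace()] with channels `T1`, `T2`, `T3`.
#' @export
simulate_stack <- function(stack, setpoint_c, ambient_c = 22,
                           duration_s = 1800, sample_rate_hz = 0.5,
                           noise_sd_c = 0.05, seed = NULL,
                           loss_coef = 0.15, outer_loss_coef = 0.3) {
  stopifnot(inherits(stack, "stack_spec"))
  if (is.null(stack$combo_tau_min)) {
    abort("stack has no measured combo_tau_min; supply one in stack_spec()",
          class = "prosthermal_validation_error")
  }
  if (setpoint_c <= ambient_c) {
    abort("setpoint_c must exceed ambient_c", class = "prosthermal_validation_error")
  }
  if (outer_loss_coef <= loss_coef) {
    abort("outer_loss_coef must exceed loss_coef",
          class = "prosthermal_validation_error")
  }
  tau2 <- stack$combo_tau_min
  tau3 <- stack$socket$tau_min
  t <- sim_time_grid(duration_s, sample_rate_hz)
  short <- duration_s < 5 * 60 * tau2
  if (short) {
    warn(sprintf("duration %.0f s covers only %.1f combination time constants (< 5)",
                 duration_s, duration_s / (60 * tau2)))
  }
  dT <- setpoint_c - ambient_c
  T2_ss <- setpoint_c - loss_coef * dT
  T3_ss <- setpoint_c - outer_loss_coef * dT
  T2 <- first_order_response(t, T_init = ambient_c, T_ss = T2_ss, tau_min = tau2)
  # T3 chases ambient + alpha3 * (T2 - ambient): target = g0 + g1 exp(-t/tau2)
  alpha3 <- (T3_ss - ambient_c) / (T2_ss - ambient_c)
  T3 <- first_order_node(t, L0 = ambient_c,
                         g0 = ambient_c + alpha3 * (T2_ss - ambient_c),
                         g1 = -alpha3 * (T2_ss - ambient_c),
                         tau_min = tau3, tau_drive_min = tau2)
  noise <- with_seed(seed, rnorm(2 * length(t), 0, noise_sd_c))
  temp_trace(
    tibble::tibble(time_s = t, T1 = setpoint_c,
                   T2 = T2 + noise[seq_along(t)],
                   T3 = T3 + noise[length(t) + seq_along(t)]),
    sample_rate_hz = sample_rate_hz,
    meta = list(liner = stack$liner$name, socket = stack$socket$name,
                combo_tau_min = tau2, outer_tau_min = tau3,
                setpoint_c = setpoint_c, ambient_c = ambient_c,
                steady_state_c = T2_ss, outer_steady_state_c = T3_ss,
                noise_sd_c = noise_sd_c, seed = seed, short_duration = short))
}
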