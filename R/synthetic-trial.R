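#' Trial protocol description
#'
#' The in-socket recording protocol: donning/resting for 10 min, treadmill
#' walking for 10 min and a final 15 min rest, sampled at 0.5 Hz in a
#' climate chamber (default 40% humidity) at a controlled ambient
#' temperature of 10, 15, 20 or 25 degrees C.
#'
#' @param rest1_min,walk_min,rest2_min Phase durations, minutes.
#' @param sample_rate_hz Logger rate, Hz.
#' @param ambient_c Chamber ambient temperature, degrees C.
#' @param humidity_pct Relative humidity (metadata only).
#' @return A list of class `trial_protocol`.
#' @export
trial_protocol <- function(rest1_min = 10, walk_min = 10, rest2_min = 15,
                           sample_rate_hz = 0.5, ambient_c = 25,
                           humidity_pct = 40) {
  if (any(c(rest1_min, walk_min, rest2_min, sample_rate_hz) <= 0)) {
    abort("durations and sample rate must be positive",
          class = "prosthermal_validation_error")
  }
  structure(list(rest1_min = rest1_min, walk_min = walk_min,
                 rest2_min = rest2_min, sample_rate_hz = sample_rate_hz,
                 ambient_c = ambient_c, humidity_pct = humidity_pct),
            class = "trial_protocol")
}

#' Physiological parameters of the synthetic trial generator
#'
#' Defaults chosen so that the generated skin traces sit in the 30-34
#' degrees C range typical of in-socket residual-limb recordings. The
#' resting skin equilibrium rises with ambient temperature
#' (`skin_eq_base_c + skin_eq_ambient_coef * ambient_c`), walking raises
#' the equilibrium by `activity_gain_c`, and skin relaxes between
#' equilibria with a physiological time constant `phase_tau_min`. The
#' liner-socket interface channel is a first-order lag of skin with the
#' stack's thermal time constant, attenuated toward ambient by
#' `liner_attenuation` (the liner asymptote is
#' `ambient + liner_attenuation * (skin - ambient)`).
#'
#' @param skin_eq_base_c,skin_eq_ambient_coef Resting skin equilibrium
#'   model (degrees C; dimensionless coefficient per degree C ambient).
#' @param donning_offset_c How far below its resting equilibrium the skin
#'   starts right after donning, degrees C.
#' @param activity_gain_c Equilibrium shift while walking, degrees C.
#' @param phase_tau_min Physiological relaxation time constant, minutes.
#' @param liner_attenuation Fraction of the skin-to-ambient difference
#'   reaching the liner interface at steady state.
#' @param noise_sd_c Sensor noise sd added to every channel, degrees C.
#' @param medial_offset_c Fixed medial-minus-lateral offset, degrees C.
#' @return A list of class `trial_params`.
#' @export
trial_params <- function(skin_eq_base_c = 29, skin_eq_ambient_coef = 0.10,
                         donning_offset_c = 0.1, activity_gain_c = 1.5,
                         phase_tau_min = 8, liner_attenuation = 0.85,
                         noise_sd_c = 0.1, medial_offset_c = 0.3) {
  if (phase_tau_min <= 0 || liner_attenuation <= 0 || liner_attenuation > 1 ||
      noise_sd_c < 0) {
    abort("invalid trial parameters", class = "prosthermal_validation_error")
  }
  structure(list(skin_eq_base_c = skin_eq_base_c,
                 skin_eq_ambient_coef = skin_eq_ambient_coef,
                 donning_offset_c = donning_offset_c,
                 activity_gain_c = activity_gain_c,
                 phase_tau_min = phase_tau_min,
                 liner_attenuation = liner_attenuation,
                 noise_sd_c = noise_sd_c,
                 medial_offset_c = medial_offset_c), class = "trial_params")
}

#' Generate a synthetic rest/walk/rest trial recording
#'
#' Produces paired residual-limb skin and liner-interface temperature
#' traces emulating the clinical protocol of [trial_protocol()]. Skin
#' follows piecewise first-order kinetics between a resting equilibrium, a
#' walking equilibrium (`+ activity_gain_c`) and back; the liner interface
#' is a first-order lag of skin with time constant `stack$combo_tau_min`,
#' attenuated toward ambient (the liner starts at ambient: it was just
#' donned). Lateral and medial sites differ by a fixed offset, and i.i.d.
#' Gaussian sensor noise is added to all four channels. The noise-free
#' channels and every generator parameter are kept alongside the noisy
#' trace, so recovery studies always have ground truth.
#'
#' @param protocol A [trial_protocol()].
#' @param stack A [stack_spec()] with `combo_tau_min` present.
#' @param params A [trial_params()].
#' @param seed Optional integer seed; the same seed reproduces the
#'   recording bit for bit.
#' @return A list of class `trial_recording` with elements `trace` (noisy
#'   [temp_trace()] with channels `skin_lateral`, `skin_medial`,
#'   `liner_lateral`, `liner_medial`), `clean` (the same channels without
#'   noise), `protocol`, and `truth` (generator parameters, stack and seed).
#' @export
#' @examples
#' rec <- generate_trial(seed = 42)
#' nrow(rec$trace)
generate_trial <- function(protocol = trial_protocol(),
                           stack = get_stack("OttoBock Technogel",
                                             "thermosetting lay-up"),
                           params = trial_params(), seed = NULL) {
  stopifnot(inherits(protocol, "trial_protocol"),
            inherits(stack, "stack_spec"), inherits(params, "trial_params"))
  if (is.null(stack$combo_tau_min)) {
    abort("stack has no measured combo_tau_min",
          class = "prosthermal_validation_error")
  }
  A <- protocol$ambient_c
  eq_rest <- params$skin_eq_base_c + params$skin_eq_ambient_coef * A
  eq_walk <- eq_rest + params$activity_gain_c
  taup <- params$phase_tau_min
  tauL <- stack$combo_tau_min
  k <- params$liner_attenuation

  total_s <- 60 * (protocol$rest1_min + protocol$walk_min + protocol$rest2_min)
  t <- sim_time_grid(total_s, protocol$sample_rate_hz)
  bounds_s <- 60 * cumsum(c(protocol$rest1_min, protocol$walk_min,
                            protocol$rest2_min))
  phase_start <- c(0, bounds_s[1], bounds_s[2])
  phase_eq <- c(eq_rest, eq_walk, eq_rest)

  skin <- numeric(length(t))
  liner <- numeric(length(t))
  S0 <- eq_rest - params$donning_offset_c
  L0 <- A
  for (p in 1:3) {
    in_phase <- t >= phase_start[p] & t < c(bounds_s, Inf)[p]
    tp <- t[in_phase] - phase_start[p]
    E <- phase_eq[p]
    skin[in_phase] <- E + (S0 - E) * exp(-tp / (60 * taup))
    liner[in_phase] <- first_order_node(tp, L0 = L0,
                                        g0 = A + k * (E - A),
                                        g1 = k * (S0 - E),
                                        tau_min = tauL, tau_drive_min = taup)
    len_s <- bounds_s[p] - phase_start[p]
    L0 <- first_order_node(len_s, L0 = L0, g0 = A + k * (E - A),
                           g1 = k * (S0 - E), tau_min = tauL,
                           tau_drive_min = taup)
    S0 <- E + (S0 - E) * exp(-len_s / (60 * taup))
  }

  off <- params$medial_offset_c
  clean <- tibble::tibble(time_s = t,
                          skin_lateral = skin,
                          skin_medial = skin + off,
                          liner_lateral = liner,
                          liner_medial = liner + off)
  noise <- with_seed(seed, rnorm(4 * length(t), 0, params$noise_sd_c))
  noisy <- clean
  for (i in 1:4) {
    noisy[[i + 1]] <- clean[[i + 1]] + noise[(i - 1) * length(t) + seq_along(t)]
  }
  meta <- list(ambient_c = A, seed = seed,
               stack = paste(stack$liner$name, stack$socket$name, sep = " + "))
  structure(list(
    trace = temp_trace(noisy, protocol$sample_rate_hz, meta),
    clean = temp_trace(clean, protocol$sample_rate_hz, meta),
    protocol = protocol,
    truth = list(params = params, stack = stack, seed = seed,
                 skin_eq_rest_c = eq_rest, skin_eq_walk_c = eq_walk,
                 liner_tau_min = tauL, phase_bounds_s = bounds_s)),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording: %s, ambient %.0f degC, %d samples @ %.2g Hz, seed %s>\n",
    trace_meta(x$trace)$stack, x$protocol$ambient_c, nrow(x$trace),
    trace_sample_rate(x$trace),
    if (is.null(x$truth$seed)) "none" else x$truth$seed))
  invisible(x)
}

#' @export
autoplot.trial_recording <- function(object, ...) {
  autoplot(object$trace) +
    ggplot2::geom_vline(xintercept = object$truth$phase_bounds_s[1:2] / 60,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(title = sprintf("synthetic trial (ambient %.0f °C)",
                                  object$protocol$ambient_c))
}
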