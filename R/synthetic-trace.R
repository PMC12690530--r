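#' Specify a sinusoidal compression loading protocol
#'
#' Defaults mirror the standard microindentation protocol for mouse
#' functional spine units: 1 Hz, 20 cycles, 35 um displacement amplitude,
#' 0.03 N preload.
#'
#' @param frequency Loading frequency in Hz (> 0).
#' @param n_cycles Number of cycles (>= 1).
#' @param amplitude Displacement amplitude in micrometres.
#' @param stiffness Sample stiffness in N/um; the force amplitude is
#'   `stiffness * amplitude`.
#' @param phase_delta Phase lag of force behind displacement, radians in
#'   \[0, pi/2). The loss tangent of the simulated material is
#'   `tan(phase_delta)`.
#' @param preload Constant force offset in N.
#' @param sample_rate Sampling rate in Hz; must be at least 20 x frequency
#'   so cycles are well resolved.
#' @param noise_sd Gaussian force noise SD in N.
#'
#' @return A `loading_protocol` list.
#' @export
loading_protocol <- function(frequency = 1, n_cycles = 20, amplitude = 35,
                             stiffness = 0.01, phase_delta = 0.1,
                             preload = 0.03, sample_rate = 100,
                             noise_sd = 0) {
  check_scalar_number(frequency, "frequency", 0, strict_lower = TRUE)
  check_scalar_number(n_cycles, "n_cycles", 1)
  check_scalar_number(amplitude, "amplitude", 0, strict_lower = TRUE)
  check_scalar_number(stiffness, "stiffness", 0, strict_lower = TRUE)
  check_scalar_number(phase_delta, "phase_delta", 0, pi / 2, strict_upper = TRUE)
  check_scalar_number(noise_sd, "noise_sd", 0)
  if (sample_rate < 20 * frequency) {
    stop_ivd("`sample_rate` must be at least 20 x frequency (aliasing guard).",
             "bad_protocol")
  }
  structure(
    list(frequency = frequency, n_cycles = as.integer(n_cycles),
         amplitude = amplitude, stiffness = stiffness,
         phase_delta = phase_delta, preload = preload,
         sample_rate = sample_rate, noise_sd = noise_sd),
    class = "loading_protocol"
  )
}

#' Simulate a cyclic-compression loading trace
#'
#' Displacement is `amplitude * sin(2*pi*f*t)`; force is
#' `preload + stiffness * amplitude * sin(2*pi*f*t + phase_delta)` plus
#' seeded Gaussian noise. The record spans exactly `n_cycles` cycles.
#'
#' @param protocol A [loading_protocol()].
#' @param seed Integer seed for the force noise.
#'
#' @return A tibble of class `loading_trace` with columns `time_s`,
#'   `displacement_um`, `force_N` and attributes `frequency` and
#'   `amplitude`.
#' @export
#' @examples
#' tr <- generate_loading_trace(loading_protocol(phase_delta = 0.1), seed = 1)
#' nrow(tr) # 20 cycles at 100 Hz
generate_loading_trace <- function(protocol, seed) {
  stopifnot(inherits(protocol, "loading_protocol"))
  p <- protocol
  n <- round(p$n_cycles * p$sample_rate / p$frequency)
  t <- (seq_len(n) - 1) / p$sample_rate
  x <- p$amplitude * sin(2 * pi * p$frequency * t)
  f0 <- p$stiffness * p$amplitude
  f <- p$preload + f0 * sin(2 * pi * p$frequency * t + p$phase_delta)
  if (p$noise_sd > 0) f <- f + with_seed(seed, rnorm(n, sd = p$noise_sd))
  out <- tibble(time_s = t, displacement_um = x, force_N = f)
  attr(out, "frequency") <- p$frequency
  attr(out, "amplitude") <- p$amplitude
  class(out) <- c("loading_trace", class(out))
  out
}

#' Simulate a glucose tolerance test (GTT) series
#'
#' Four-point blood glucose series at 0, 30, 60 and 90 minutes post
#' injection (reported in hours: 0, 0.5, 1.0, 1.5 h), with optional seeded
#' measurement noise.
#'
#' @param baseline Fasting glucose at t = 0, mg/dl (> 0).
#' @param peaks Numeric vector of 3 glucose values at 30/60/90 min, mg/dl.
#' @param noise_sd Gaussian measurement noise SD in mg/dl (default 0).
#' @param seed Integer seed for the noise.
#'
#' @return A tibble with columns `time_h` and `glucose_mg_dl`.
#' @export
#' @examples
#' generate_gtt_series(200, c(400, 400, 300), seed = 1)
generate_gtt_series <- function(baseline, peaks, noise_sd = 0, seed = 1) {
  check_scalar_number(baseline, "baseline", 0, strict_lower = TRUE)
  if (length(peaks) != 3 || any(!is.finite(peaks)) || any(peaks <= 0)) {
    stop_ivd("`peaks` must give 3 positive glucose values (30/60/90 min).",
             "bad_gtt")
  }
  check_scalar_number(noise_sd, "noise_sd", 0)
  g <- c(baseline, peaks)
  if (noise_sd > 0) {
    g <- g + with_seed(seed, rnorm(4, sd = noise_sd))
    g <- pmax(g, 1)  # glucose cannot go non-positive
  }
  tibble(time_h = c(0, 0.5, 1.0, 1.5), glucose_mg_dl = g)
}
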