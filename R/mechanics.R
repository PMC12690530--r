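trace_freq <- function(trace, frequency = NULL) {
  f <- frequency %||% attr(trace, "frequency")
  if (is.null(f)) {
    # fall back to the dominant period from mean-centred zero crossings
    cyc <- extract_cycles(trace)
    f <- 1 / mean(diff(vapply(cyc$segments, function(s) trace$time_s[s[1]], numeric(1))))
  }
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "displacement_um", "force_N") %in% names(trace)))
  t <- trace$time_s
  if (any(diff(t) <= 0)) stop_ivd("Trace time must be strictly increasing.", "bad_trace")
  dt <- diff(t)
  if ((max(dt) - min(dt)) / median(dt) > 0.05) {
    stop_ivd("Trace sampling must be uniform (within a few % jitter).", "bad_trace")
  }
  invisible(trace)
}

#' Split a cyclic-compression trace into cycles
#'
#' Cycle boundaries are the positive-going zero crossings of the
#' mean-centred displacement; a leading boundary is added when the record
#' starts on an ascending zero, and the trailing segment is kept when it
#' spans at least 95% of the median cycle length. Tolerant of ~1% timing
#' jitter.
#'
#' @param trace A loading-trace data frame (`time_s`, `displacement_um`,
#'   `force_N`).
#'
#' @return A list: `segments` (list of sample-index ranges `c(start, end)`,
#'   one per cycle) and `n_cycles`.
#' @export
extract_cycles <- function(trace) {
  check_trace(trace)
  x <- trace$displacement_um - mean(trace$displacement_um)
  n <- length(x)
  if (all(abs(x) < 1e-12)) {
    stop_ivd("Displacement is constant: no cycles to extract.", "bad_trace")
  }
  up <- which(x[-n] < 0 & x[-1] >= 0) + 1L
  starts <- up
  if (x[1] >= 0 && n > 1 && x[2] > x[1]) starts <- c(1L, starts)
  starts <- unique(starts)
  if (length(starts) < 2) {
    stop_ivd("Fewer than 2 cycles detected.", "too_few_cycles")
  }
  period <- median(diff(starts))
  ends <- c(starts[-1] - 1L, n)
  keep <- (ends - starts + 1L) >= 0.95 * period
  segments <- purrr::map2(starts[keep], ends[keep], c)
  if (length(segments) < 2) {
    stop_ivd("Fewer than 2 complete cycles detected.", "too_few_cycles")
  }
  list(segments = segments, n_cycles = length(segments))
}

# Resolve a cycle selection: "all", "lastK", or an integer vector.
select_cycles <- function(cycles, selection) {
  n <- cycles$n_cycles
  if (is.character(selection)) {
    if (identical(selection, "all")) return(seq_len(n))
    m <- regmatches(selection, regexec("^last([0-9]+)$", selection))[[1]]
    if (length(m) == 2) {
      k <- min(as.integer(m[2]), n)
      return(seq.int(n - k + 1L, n))
    }
    stop_ivd("Cycle selection must be 'all', 'last<k>' or indices.", "bad_argument")
  }
  sel <- as.integer(selection)
  if (any(sel < 1 | sel > n)) stop_ivd("Cycle index out of range.", "bad_argument")
  sel
}

#' Loading slope from the linear region of the force-displacement curve
#'
#' On each selected cycle's loading branch (samples from the displacement
#' minimum to the following maximum), a least-squares line is fitted to
#' force versus displacement over the central 20-80% of the displacement
#' range — the operational definition of the "linear region" — and slopes
#' are averaged over the selected cycles. Steady-state cycles (the last 10)
#' are used by default to skip preconditioning transients.
#'
#' @param trace A loading-trace data frame.
#' @param cycles Cycle selection: `"all"`, `"last<k>"` (default
#'   `"last10"`), or integer indices.
#'
#' @return Slope in N/um.
#' @export
loading_slope <- function(trace, cycles = "last10") {
  check_trace(trace)
  cyc <- extract_cycles(trace)
  sel <- select_cycles(cyc, cycles)
  slopes <- vapply(sel, function(i) {
    seg <- cyc$segments[[i]]
    idx <- seg[1]:seg[2]
    x <- trace$displacement_um[idx]
    f <- trace$force_N[idx]
    i_min <- which.min(x)
    i_max <- which.max(x)
    branch <- if (i_min <= i_max) i_min:i_max else i_max:i_min
    xb <- x[branch]; fb <- f[branch]
    rng <- range(xb)
    span <- diff(rng)
    keep <- xb >= rng[1] + 0.2 * span & xb <= rng[1] + 0.8 * span
    if (sum(keep) < 5) {
      stop_ivd("Loading branch has fewer than 5 samples in the linear region.",
               "too_few_samples")
    }
    unname(coef(lm(fb[keep] ~ xb[keep]))[2])
  }, numeric(1))
  mean(slopes)
}

# Least-squares single-frequency sinusoid fit: y ~ a*sin(wt) + b*cos(wt) + c.
# Returns amplitude, phase (y = R*sin(wt + phase)), offset, and the ratio
# of residual power to signal power.
fit_sinusoid <- function(t, y, freq) {
  w <- 2 * pi * freq
  s <- sin(w * t); cc <- cos(w * t)
  fit <- lm(y ~ s + cc)
  a <- coef(fit)[["s"]]; b <- coef(fit)[["cc"]]
  amplitude <- sqrt(a^2 + b^2)
  resid_power <- mean(fit$residuals^2)
  signal_power <- amplitude^2 / 2
  list(amplitude = amplitude, phase = atan2(b, a),
       offset = coef(fit)[[1]],
       resid_ratio = if (signal_power > 0) resid_power / signal_power else Inf)
}

#' Loss tangent from the force-displacement phase delay
#'
#' Fits single-frequency sinusoids (amplitude, phase, offset) to
#' displacement and force by linear least squares on sin/cos regressors at
#' the nominal frequency, over the selected cycles; the loss tangent is
#' `tan(phase_force - phase_displacement)` with the phase difference
#' wrapped to \[0, pi/2). Zero for a purely elastic sample. Non-sinusoidal
#' input (fit residual power above 50% of signal power) is an error.
#'
#' @param trace A loading-trace data frame.
#' @param cycles Cycle selection (default `"last10"`).
#' @param frequency Nominal loading frequency in Hz; defaults to the
#'   trace's `frequency` attribute, or is estimated from zero crossings.
#'
#' @return `tan_delta` (dimensionless, >= 0).
#' @export
tan_delta <- function(trace, cycles = "last10", frequency = NULL) {
  check_trace(trace)
  cyc <- extract_cycles(trace)
  if (cyc$n_cycles < 5) stop_ivd("Need at least 5 full cycles.", "too_few_cycles")
  sel <- select_cycles(cyc, cycles)
  idx <- unlist(lapply(cyc$segments[sel], function(s) s[1]:s[2]))
  f <- trace_freq(trace, frequency)
  fit_x <- fit_sinusoid(trace$time_s[idx], trace$displacement_um[idx], f)
  fit_f <- fit_sinusoid(trace$time_s[idx], trace$force_N[idx], f)
  if (fit_x$resid_ratio > 0.5 || fit_f$resid_ratio > 0.5) {
    stop_ivd("Trace is not sinusoidal at the nominal frequency.", "bad_fit")
  }
  d <- fit_f$phase - fit_x$phase
  d <- atan2(sin(d), cos(d))  # wrap to (-pi, pi]
  if (d < -1e-6 || d >= pi / 2) {
    stop_ivd("Phase delay outside [0, pi/2): non-physical trace.", "bad_fit")
  }
  max(tan(d), 0)
}

#' Hysteresis energy per cycle of the force-displacement loop
#'
#' Absolute signed (shoelace) area of each selected cycle's closed
#' force-displacement loop, averaged over the selection; the energy
#' dissipated per cycle in N.um. For a phase-lagged sinusoid this equals
#' `pi * F0 * X0 * sin(delta)`.
#'
#' @param trace A loading-trace data frame.
#' @param cycles Cycle selection (default `"last10"`).
#'
#' @return Mean loop area in N.um.
#' @export
hysteresis_energy <- function(trace, cycles = "last10") {
  check_trace(trace)
  cyc <- extract_cycles(trace)
  sel <- select_cycles(cyc, cycles)
  areas <- vapply(sel, function(i) {
    seg <- cyc$segments[[i]]
    idx <- seg[1]:seg[2]
    x <- trace$displacement_um[idx]
    f <- trace$force_N[idx]
    nn <- length(x)
    if (nn < 8) stop_ivd("Cycle too short for a closed loop.", "too_few_samples")
    j <- c(2:nn, 1L)  # close the loop back to the cycle start
    abs(sum(x * f[j] - x[j] * f) / 2)
  }, numeric(1))
  mean(areas)
}

#' Full viscoelastic analysis of one loading trace
#'
#' Computes the loading slope, loss tangent and per-cycle hysteresis
#' energy on a common cycle selection and returns a fitted-result object
#' with [tidy()] and [glance()] methods.
#'
#' @inheritParams tan_delta
#' @return A `viscoelastic_fit` object.
#' @export
#' @examples
#' tr <- generate_loading_trace(loading_protocol(phase_delta = 0.1), seed = 1)
#' glance(viscoelastic_analysis(tr))
viscoelastic_analysis <- function(trace, cycles = "last10", frequency = NULL) {
  cyc <- extract_cycles(trace)
  sel <- select_cycles(cyc, cycles)
  structure(
    list(
      loading_slope = loading_slope(trace, cycles),
      tan_delta = tan_delta(trace, cycles, frequency),
      hysteresis_energy = hysteresis_energy(trace, cycles),
      cycles_used = sel, n_cycles = cyc$n_cycles,
      frequency = trace_freq(trace, frequency)
    ),
    class = "viscoelastic_fit"
  )
}

#' @export
print.viscoelastic_fit <- function(x, ...) {
  cat(sprintf(paste0("<viscoelastic_fit> slope %.4g N/um, tan delta %.4g, ",
                     "energy %.4g N.um (cycles %d-%d of %d)\n"),
              x$loading_slope, x$tan_delta, x$hysteresis_energy,
              min(x$cycles_used), max(x$cycles_used), x$n_cycles))
  invisible(x)
}

#' @export
tidy.viscoelastic_fit <- function(x, ...) {
  tibble(
    term = c("loading_slope", "tan_delta", "hysteresis_energy"),
    estimate = c(x$loading_slope, x$tan_delta, x$hysteresis_energy),
    unit = c("N/um", "", "N.um")
  )
}

#' @export
glance.viscoelastic_fit <- function(x, ...) {
  tibble(loading_slope = x$loading_slope, tan_delta = x$tan_delta,
         hysteresis_energy = x$hysteresis_energy,
         n_cycles = x$n_cycles, n_cycles_used = length(x$cycles_used),
         frequency = x$frequency)
}
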