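#' Biphasic charge-balanced pulse specification
#'
#' Rectangular two-phase current stimulus: a leading phase of amplitude
#' `i_amp` and duration `t0`, an optional interphase gap, then an
#' equal-and-opposite second phase. Net charge is zero.
#'
#' @param i_amp Current amplitude, ampere, > 0.
#' @param t0 Phase duration, seconds, > 0.
#' @param gap Interphase gap, seconds, >= 0 (default 0, the in-vitro case).
#' @param polarity `"cathodic"` (leading phase negative, the clinical
#'   default) or `"anodic"`.
#' @return An object of class `pulse_spec`.
#' @examples
#' pulse_spec(i_amp = 50e-6, t0 = 50e-6)               # in-vitro stimulus
#' pulse_spec(i_amp = 125e-6, t0 = 25e-6, gap = 9e-6)  # implant telemetry pulse
#' @export
pulse_spec <- function(i_amp, t0, gap = 0, polarity = c("cathodic", "anodic")) {
  polarity <- match.arg(polarity)
  stopifnot(i_amp > 0, t0 > 0, gap >= 0)
  structure(list(i_amp = i_amp, t0 = t0, gap = gap, polarity = polarity),
            class = "pulse_spec")
}

# step times and signed step amplitudes of the pulse's current trace
# (cathodic-leading; caller negates for anodic)
pulse_steps <- function(pulse) {
  list(times = c(0, pulse$t0, pulse$t0 + pulse$gap, 2 * pulse$t0 + pulse$gap),
       amps = pulse$i_amp * c(-1, 1, 1, -1))
}

check_uniform <- function(times) {
  if (length(times) < 2) stop("need at least two time samples")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1])) {
    stop("time grid must be uniform")
  }
  dt[1]
}

#' Time-domain biphasic current trace
#'
#' Evaluates the stimulus current on a uniform time grid. Switching instants
#' take the right-limit value (the sample at a phase boundary belongs to the
#' segment that starts there).
#'
#' @param pulse A [pulse_spec()].
#' @param times Uniform time grid, seconds; pulse onset is at t = 0.
#' @return Numeric current trace, ampere.
#' @export
biphasic_current <- function(pulse, times) {
  stopifnot(inherits(pulse, "pulse_spec"))
  check_uniform(times)
  st <- pulse_steps(pulse)
  i <- numeric(length(times))
  for (k in seq_along(st$times)) {
    i <- i + st$amps[k] * (times >= st$times[k])
  }
  if (pulse$polarity == "anodic") i <- -i
  i
}

#' Voltage waveform container
#'
#' @param times Uniform time grid, seconds.
#' @param mean_v Mean voltage across repeats, volt.
#' @param std_v Standard deviation across repeats, volt (zeros for
#'   simulated waveforms).
#' @param sampling_rate Sampling rate, Hz.
#' @param onset_time Pulse onset on the time grid, seconds, or NA when not
#'   yet aligned (see [detect_onset()]).
#' @return An object of class `voltage_waveform`.
#' @export
voltage_waveform <- function(times, mean_v, std_v = NULL,
                             sampling_rate = 1 / check_uniform(times),
                             onset_time = NA_real_) {
  stopifnot(length(mean_v) == length(times))
  check_uniform(times)
  if (any(!is.finite(mean_v))) stop("mean_v must be finite everywhere")
  if (is.null(std_v)) std_v <- numeric(length(times))
  structure(list(times = times, mean_v = mean_v, std_v = std_v,
                 sampling_rate = sampling_rate, onset_time = onset_time),
            class = "voltage_waveform")
}

#' @export
print.voltage_waveform <- function(x, ...) {
  cat("<voltage_waveform> ", length(x$times), " samples @ ",
      format(x$sampling_rate / 1e6, digits = 4), " MHz, onset ",
      if (is.na(x$onset_time)) "unset" else paste0(format(x$onset_time * 1e6, digits = 4), " us"),
      "\n", sep = "")
  invisible(x)
}

# unit-current step response of the full circuit, right-limit convention:
# r(t) = t^p / (Y Gamma(p+1)) + R1 (1 - exp(-t/(R1 C))) + R2   for t >= 0
step_response <- function(params, t) {
  p <- params$cpe_p
  out <- numeric(length(t))
  on <- t >= 0
  tt <- t[on]
  out[on] <- tt^p / (params$cpe_t * gamma(p + 1)) +
    params$r1 * (1 - exp(-tt / (params$r1 * params$c))) +
    params$r2
  out
}

#' Closed-form voltage response to a biphasic pulse
#'
#' Superposes shifted copies of the circuit's analytic unit-step response
#' `r(t) = t^p/(Y Gamma(p+1)) + R1 (1 - exp(-t/(R1 C))) + R2`, one per
#' current step of the stimulus. With zero interphase gap this is the
#' three-term inverse-Laplace solution
#' `V(t) = -i_amp [r(t)u(t) - 2 r(t-T0)u(t-T0) + r(t-2T0)u(t-2T0)]`
#' (cathodic-leading); a positive gap contributes four shifted terms.
#' Samples at switching instants take the right-limit value.
#'
#' @param params A [circuit_params()].
#' @param pulse A [pulse_spec()].
#' @param times Uniform time grid, seconds; onset at t = 0; V = 0 for t < 0.
#' @return A [voltage_waveform()] with `onset_time = 0`.
#' @export
simulate_waveform <- function(params, pulse, times) {
  stopifnot(inherits(params, "circuit_params"), inherits(pulse, "pulse_spec"))
  check_uniform(times)
  st <- pulse_steps(pulse)
  v <- numeric(length(times))
  for (k in seq_along(st$times)) {
    v <- v + st$amps[k] * step_response(params, times - st$times[k])
  }
  if (pulse$polarity == "anodic") v <- -v
  voltage_waveform(times, v, sampling_rate = 1 / check_uniform(times),
                   onset_time = 0)
}

# Gaver-Stehfest weights for even n
stehfest_weights <- function(n = 14L) {
  stopifnot(n %% 2 == 0)
  v <- numeric(n)
  nh <- n / 2
  for (k in seq_len(n)) {
    s <- 0
    for (j in floor((k + 1) / 2):min(k, nh)) {
      s <- s + j^nh * factorial(2 * j) /
        (factorial(nh - j) * factorial(j) * factorial(j - 1) *
           factorial(k - j) * factorial(2 * j - k))
    }
    v[k] <- (-1)^(k + nh) * s
  }
  v
}

# numeric unit-current step response by Gaver-Stehfest inversion of Z(s)/s
step_response_numeric <- function(params, t, n_stehfest = 14L) {
  w <- stehfest_weights(n_stehfest)
  zs <- function(s) {
    1 / (params$cpe_t * s^params$cpe_p) +
      params$r1 / (1 + s * params$r1 * params$c) + params$r2
  }
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  if (length(tp)) {
    acc <- numeric(length(tp))
    ln2t <- log(2) / tp
    for (k in seq_along(w)) {
      s <- k * ln2t
      acc <- acc + w[k] * zs(s) / s
    }
    out[pos] <- ln2t * acc
  }
  # initial-value theorem: r(0+) = lim_{s->inf} Z(s) = R2
  out[t == 0] <- params$r2
  out
}

#' Voltage response by numerical Laplace inversion (test oracle)
#'
#' Independent backend for validating [simulate_waveform()]: the circuit's
#' unit-step response is obtained by Gaver-Stehfest numerical inversion of
#' `Z(s)/s`, then shifted copies are superposed per current step of the
#' stimulus. Intended for testing, not production use.
#'
#' @inheritParams simulate_waveform
#' @param n_stehfest Even number of Gaver-Stehfest terms (default 14).
#' @return A [voltage_waveform()].
#' @export
simulate_waveform_numeric <- function(params, pulse, times, n_stehfest = 14L) {
  stopifnot(inherits(params, "circuit_params"), inherits(pulse, "pulse_spec"))
  check_uniform(times)
  st <- pulse_steps(pulse)
  v <- numeric(length(times))
  for (k in seq_along(st$times)) {
    tk <- times - st$times[k]
    v <- v + st$amps[k] * step_response_numeric(params, tk, n_stehfest)
  }
  if (pulse$polarity == "anodic") v <- -v
  voltage_waveform(times, v, sampling_rate = 1 / check_uniform(times),
                   onset_time = 0)
}
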