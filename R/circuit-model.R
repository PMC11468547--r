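#' Impedance of a constant phase element
#'
#' The CPE generalises an ideal capacitor: `Z_CPE = 1 / (Y (j w)^p)` with
#' `w = 2 pi f`. Its phase angle is `-p * 90` degrees at every frequency —
#' hence "constant phase". At `p = 1` it is an ideal capacitor of value `Y`.
#'
#' @param cpe_t CPE magnitude Y (S·s^p), > 0.
#' @param cpe_p CPE exponent p in (0, 1].
#' @param frequency Frequency in Hz, > 0 (vectorised).
#' @return Complex impedance, ohm.
#' @examples
#' Arg(cpe_impedance(1e-7, 0.8, 100)) * 180 / pi  # -72 degrees
#' @export
cpe_impedance <- function(cpe_t, cpe_p, frequency) {
  if (any(frequency <= 0)) stop("frequency must be positive")
  if (cpe_t <= 0 || cpe_p <= 0 || cpe_p > 1) {
    stop("require cpe_t > 0 and cpe_p in (0, 1]")
  }
  w <- 2 * pi * frequency
  1 / (cpe_t * (1i * w)^cpe_p)
}

#' Total impedance of the CPE + R1||C + R2 circuit
#'
#' `Z(w) = 1/(Y (jw)^p) + R1/(1 + jw R1 C) + R2`. The CPE dominates at low
#' frequency, the parallel R1/C block rolls off in the mid band, and R2 is
#' the high-frequency plateau.
#'
#' @param params A [circuit_params()] object.
#' @param frequency Frequency in Hz, > 0 (vectorised).
#' @return Complex impedance, ohm.
#' @export
circuit_impedance <- function(params, frequency) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(frequency <= 0)) stop("frequency must be positive")
  w <- 2 * pi * frequency
  s <- 1i * w
  1 / (params$cpe_t * s^params$cpe_p) +
    params$r1 / (1 + s * params$r1 * params$c) +
    params$r2
}

#' Total impedance of the legacy access/polarization circuit
#'
#' `Z(w) = R_access + R_pol/(1 + jw R_pol C_pol)`.
#'
#' @param params A [simple_circuit_params()] object.
#' @param frequency Frequency in Hz, > 0 (vectorised).
#' @return Complex impedance, ohm.
#' @export
simple_circuit_impedance <- function(params, frequency) {
  stopifnot(inherits(params, "simple_circuit_params"))
  if (any(frequency <= 0)) stop("frequency must be positive")
  s <- 1i * 2 * pi * frequency
  params$r_access + params$r_pol / (1 + s * params$r_pol * params$c_pol)
}

#' Heuristic start values for circuit fitting from a measured spectrum
#'
#' Reproduces the instrument-era start-value recipe: the CPE exponent is set
#' to `cpe_p_init` (0.8 by default); the CPE magnitude Y is solved from the
#' CPE impedance formula at 10 Hz assuming the CPE carries the whole
#' magnitude there, `Y = 1 / (|Z(10 Hz)| w^p)`; both resistors start at the
#' 100 kHz magnitude; and C is solved from the ideal-capacitor formula at
#' 10 Hz, `C = 1 / (w |Z(10 Hz)|)`. These are heuristics for the optimiser,
#' never constraints on the fit.
#'
#' If the exact anchor frequencies are absent the nearest available
#' frequency is substituted with a warning, provided it lies within a
#' quarter decade; otherwise an error names the missing frequency.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param cpe_p_init Start value for the CPE exponent (default 0.8).
#' @return A [circuit_params()] object of start values.
#' @export
start_values <- function(spectrum, cpe_p_init = 0.8) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  z_lo <- mag_at(spectrum, 10)
  z_hi <- mag_at(spectrum, 1e5)
  w_lo <- 2 * pi * 10
  circuit_params(
    cpe_t = 1 / (z_lo * w_lo^cpe_p_init),
    cpe_p = cpe_p_init,
    r1 = z_hi,
    c = 1 / (w_lo * z_lo),
    r2 = z_hi
  )
}

# magnitude at (or nearest to) a target frequency; errors beyond 1/4 decade
mag_at <- function(spectrum, f_target) {
  i <- which.min(abs(log10(spectrum$frequencies) - log10(f_target)))
  off <- abs(log10(spectrum$frequencies[i]) - log10(f_target))
  if (off > 0.25) {
    stop(sprintf("spectrum has no point near %g Hz (closest: %g Hz)",
                 f_target, spectrum$frequencies[i]))
  }
  if (off > 1e-9) {
    warning(sprintf("no point at exactly %g Hz; using nearest (%g Hz)",
                    f_target, spectrum$frequencies[i]))
  }
  spectrum$z_mag[i]
}

#' Evaluate a circuit model as an impedance spectrum
#'
#' @param params [circuit_params()] or [simple_circuit_params()].
#' @param frequencies Frequencies, Hz.
#' @return An [impedance_spectrum()] of the noise-free model curve.
#' @export
model_spectrum <- function(params, frequencies = eis_frequency_grid()) {
  z <- if (inherits(params, "circuit_params")) {
    circuit_impedance(params, frequencies)
  } else {
    simple_circuit_impedance(params, frequencies)
  }
  impedance_spectrum(frequencies, Mod(z), Arg(z) * 180 / pi)
}
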