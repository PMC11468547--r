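#' Frequency grid for impedance sweeps
#'
#' Log-spaced measurement grid: 10 frequencies per decade from `f_min` to
#' `f_max`, inclusive of both endpoints. The default sweep (10 Hz to
#' 100 kHz) has 41 points.
#'
#' @param f_min,f_max Sweep endpoints in Hz.
#' @param per_decade Points per decade.
#' @return Numeric vector of frequencies, strictly ascending, Hz.
#' @examples
#' length(eis_frequency_grid())  # 41
#' @export
eis_frequency_grid <- function(f_min = 10, f_max = 1e5, per_decade = 10) {
  stopifnot(f_min > 0, f_max > f_min, per_decade >= 1)
  n <- round(per_decade * log10(f_max / f_min)) + 1L
  10^seq(log10(f_min), log10(f_max), length.out = n)
}

#' Impedance spectrum container
#'
#' Stores a frequency-indexed complex impedance in instrument form:
#' magnitude (ohm) and phase angle (degrees, negative for capacitive
#' behaviour), with optional per-frequency standard deviations across
#' measurement repeats.
#'
#' @param frequencies Frequencies in Hz, strictly ascending.
#' @param z_mag Impedance magnitude per frequency, ohm, > 0.
#' @param phase_deg Phase angle per frequency, degrees, in (-90, 90].
#' @param mag_std,phase_std Optional per-frequency standard deviations of
#'   magnitude and phase across repeats.
#' @return An object of class `impedance_spectrum`.
#' @seealso [spectrum_z()] for the complex representation.
#' @export
impedance_spectrum <- function(frequencies, z_mag, phase_deg,
                               mag_std = NULL, phase_std = NULL) {
  n <- length(frequencies)
  stopifnot(length(z_mag) == n, length(phase_deg) == n)
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing")
  if (any(z_mag <= 0)) stop("impedance magnitude must be positive")
  if (any(phase_deg <= -90 | phase_deg > 90)) {
    stop("phase angle must lie in (-90, 90] degrees")
  }
  if (!is.null(mag_std)) stopifnot(length(mag_std) == n, all(mag_std >= 0))
  if (!is.null(phase_std)) stopifnot(length(phase_std) == n, all(phase_std >= 0))
  structure(list(frequencies = frequencies, z_mag = z_mag,
                 phase_deg = phase_deg, mag_std = mag_std,
                 phase_std = phase_std),
            class = "impedance_spectrum")
}

#' Complex impedance of a spectrum
#'
#' @param spectrum An [impedance_spectrum()].
#' @return Complex vector, ohm.
#' @export
spectrum_z <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  th <- spectrum$phase_deg * pi / 180
  complex(modulus = spectrum$z_mag, argument = th)
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat("<impedance_spectrum> ", length(x$frequencies), " frequencies, ",
      format(min(x$frequencies), digits = 4), "-",
      format(max(x$frequencies), digits = 4), " Hz\n", sep = "")
  invisible(x)
}

#' EIS recording: repeated sweeps for one electrode and timepoint
#'
#' @param electrode_id Electrode identifier (character or integer).
#' @param day Integer study day, >= 0.
#' @param repeats List of [impedance_spectrum()] objects (nominally 3),
#'   all sharing one frequency grid.
#' @param construct_on Logical: was the tissue construct still covering the
#'   electrode at this timepoint?
#' @return An object of class `eis_recording`.
#' @export
eis_recording <- function(electrode_id, day, repeats, construct_on = TRUE) {
  stopifnot(length(day) == 1, day >= 0, is.list(repeats), length(repeats) >= 1)
  f0 <- repeats[[1]]$frequencies
  for (r in repeats) {
    if (!inherits(r, "impedance_spectrum")) stop("repeats must be impedance_spectrum objects")
    if (!isTRUE(all.equal(r$frequencies, f0))) {
      stop("all repeats must share one frequency grid")
    }
  }
  structure(list(electrode_id = electrode_id, day = as.integer(day),
                 repeats = repeats, construct_on = isTRUE(construct_on)),
            class = "eis_recording")
}

#' Mean spectrum across repeats of a recording
#'
#' Arithmetic mean of magnitude and of phase per frequency, with per-frequency
#' standard deviations attached; downstream fitting consumes this mean.
#'
#' @param recording An [eis_recording()].
#' @return An [impedance_spectrum()] with `mag_std` and `phase_std` filled
#'   (NULL when only one repeat is present).
#' @export
mean_spectrum <- function(recording) {
  stopifnot(inherits(recording, "eis_recording"))
  mags <- sapply(recording$repeats, function(s) s$z_mag)
  phs <- sapply(recording$repeats, function(s) s$phase_deg)
  if (is.null(dim(mags))) { mags <- cbind(mags); phs <- cbind(phs) }
  n_rep <- ncol(mags)
  impedance_spectrum(
    frequencies = recording$repeats[[1]]$frequencies,
    z_mag = rowMeans(mags),
    phase_deg = rowMeans(phs),
    mag_std = if (n_rep >= 2) apply(mags, 1, stats::sd) else NULL,
    phase_std = if (n_rep >= 2) apply(phs, 1, stats::sd) else NULL
  )
}
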