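phase_window <- function(waveform, from, to) {
  idx <- which(waveform$times >= from & waveform$times < to)
  if (length(idx) == 0 ||
      from < waveform$times[1] - 1e-12 ||
      to > waveform$times[length(waveform$times)] + 1 / waveform$sampling_rate) {
    stop("phase window [", from, ", ", to, ") s lies outside the record")
  }
  idx
}

require_onset <- function(waveform) {
  if (is.na(waveform$onset_time)) {
    stop("waveform is not aligned; run detect_onset()/align_waveform() first")
  }
  waveform$onset_time
}

#' Clinical contact "impedance" from a voltage waveform
#'
#' The telemetry quantity reported by implant software: the voltage peak of
#' the first phase of a cathodic-leading biphasic pulse divided by the
#' input current amplitude. Not a true frequency-resolved impedance.
#'
#' @param waveform An aligned [voltage_waveform()] (onset known).
#' @param pulse The [pulse_spec()] used for stimulation.
#' @return Contact impedance, ohm.
#' @export
contact_impedance <- function(waveform, pulse) {
  stopifnot(inherits(pulse, "pulse_spec"))
  onset <- require_onset(waveform)
  w1 <- phase_window(waveform, onset, onset + pulse$t0)
  max(abs(waveform$mean_v[w1])) / pulse$i_amp
}

#' Second phase peak ratio (SPPR)
#'
#' The second-phase voltage peak as a percentage of the first-phase voltage
#' peak. The second-phase peak is the extremum of the opposite-polarity
#' excursion; magnitudes are used throughout, so the marker is invariant to
#' pulse polarity and current amplitude. As bulk capacitance falls during
#' fibrotic encapsulation the capacitive discharge contribution to the
#' second phase shrinks and SPPR rises toward its resistive asymptote.
#'
#' @inheritParams contact_impedance
#' @return SPPR, percent.
#' @export
sppr <- function(waveform, pulse) {
  stopifnot(inherits(pulse, "pulse_spec"))
  onset <- require_onset(waveform)
  w1 <- phase_window(waveform, onset, onset + pulse$t0)
  w2 <- phase_window(waveform, onset + pulse$t0 + pulse$gap,
                     onset + 2 * pulse$t0 + pulse$gap)
  v <- waveform$mean_v
  i1 <- w1[which.max(abs(v[w1]))]
  peak1 <- abs(v[i1])
  if (peak1 == 0) stop("zero first-phase peak; SPPR undefined")
  s1 <- sign(v[i1])
  peak2 <- max(c(0, -s1 * v[w2]))
  100 * peak2 / peak1
}

#' Patient telemetry record
#'
#' Voltages sampled at fixed offsets inside each phase of the telemetry
#' pulse, as exported per electrode and visit by clinical fitting software.
#'
#' @param patient_id Patient identifier.
#' @param electrode Electrode number (1-22).
#' @param visit Visit label (e.g. "intraoperative", "3 months", "5 months").
#' @param phase1,phase2 Data frames with columns `offset_us` (positive, less
#'   than the phase duration) and `voltage_v`. Signed voltages are accepted;
#'   magnitudes are taken when computing markers.
#' @param input_current Stimulus current amplitude, ampere, > 0.
#' @param mcl_cl Optional most-comfortable-loudness level in CL units.
#' @return An object of class `patient_telemetry`.
#' @export
patient_telemetry <- function(patient_id, electrode, visit, phase1, phase2,
                              input_current, mcl_cl = NA_real_) {
  for (ph in list(phase1, phase2)) {
    stopifnot(is.data.frame(ph), all(c("offset_us", "voltage_v") %in% names(ph)),
              all(ph$offset_us > 0))
  }
  stopifnot(input_current > 0)
  structure(list(patient_id = patient_id, electrode = as.integer(electrode),
                 visit = visit, phase1 = phase1, phase2 = phase2,
                 input_current = input_current, mcl_cl = mcl_cl),
            class = "patient_telemetry")
}

telemetry_voltage <- function(phase, offset_us, label) {
  i <- which(abs(phase$offset_us - offset_us) < 1e-6)
  if (length(i) == 0) {
    stop("no ", label, " sample at ", offset_us, " us offset")
  }
  phase$voltage_v[i[1]]
}

#' Altered SPPR from patient telemetry
#'
#' Clinical software cannot sample the exact end of the second phase, so the
#' patient-side SPPR variant uses the voltages 6 us into each phase:
#' `100 * |v(phase 2, 6 us)| / |v(phase 1, 6 us)|`.
#'
#' @param telemetry A [patient_telemetry()].
#' @param offset_us Offset into each phase, microseconds (default 6).
#' @return Altered SPPR, percent.
#' @export
altered_sppr <- function(telemetry, offset_us = 6) {
  stopifnot(inherits(telemetry, "patient_telemetry"))
  v1 <- abs(telemetry_voltage(telemetry$phase1, offset_us, "phase-1"))
  v2 <- abs(telemetry_voltage(telemetry$phase2, offset_us, "phase-2"))
  if (v1 == 0) stop("zero phase-1 voltage; altered SPPR undefined")
  100 * v2 / v1
}

#' Contact impedance from patient telemetry
#'
#' As computed clinically: the voltage magnitude at the end of the first
#' phase (25 us into it for the telemetry pulse) normalised to the input
#' current.
#'
#' @param telemetry A [patient_telemetry()].
#' @param offset_us Offset of the end-of-phase sample, microseconds
#'   (default 25).
#' @return Contact impedance, ohm.
#' @export
patient_contact_impedance <- function(telemetry, offset_us = 25) {
  stopifnot(inherits(telemetry, "patient_telemetry"))
  abs(telemetry_voltage(telemetry$phase1, offset_us, "phase-1")) /
    telemetry$input_current
}

#' Marker series for one electrode
#'
#' @param electrode_id Electrode identifier.
#' @param days Integer study days.
#' @param contact_impedance_ohm Contact impedance per day, ohm.
#' @param sppr_pct SPPR per day, percent (>= 0).
#' @param construct_on Logical per day.
#' @return A data frame of class `marker_series`.
#' @export
marker_series <- function(electrode_id, days, contact_impedance_ohm,
                          sppr_pct, construct_on = TRUE) {
  n <- length(days)
  stopifnot(length(contact_impedance_ohm) == n, length(sppr_pct) == n,
            all(sppr_pct >= 0, na.rm = TRUE))
  construct_on <- rep_len(construct_on, n)
  structure(data.frame(electrode_id = electrode_id, day = as.integer(days),
                       construct_on = construct_on,
                       contact_impedance_ohm = contact_impedance_ohm,
                       sppr_pct = sppr_pct),
            class = c("marker_series", "data.frame"))
}

#' Normalise a marker series to a baseline day
#'
#' Adds relative columns (`rel_contact_impedance`, `rel_sppr`): each marker
#' divided by its value at the baseline day, so the baseline maps to
#' exactly 1. Recomputing is idempotent.
#'
#' @param series A [marker_series()].
#' @param baseline_day Day used as the denominator (default 2).
#' @return The series with relative columns added.
#' @export
normalize_series <- function(series, baseline_day = 2) {
  stopifnot(inherits(series, "marker_series"))
  i <- which(series$day == baseline_day)
  if (length(i) != 1) {
    stop("baseline day ", baseline_day, " not present (exactly once) in series")
  }
  series$rel_contact_impedance <-
    series$contact_impedance_ohm / series$contact_impedance_ohm[i]
  series$rel_sppr <- series$sppr_pct / series$sppr_pct[i]
  series
}

#' Linear SPPR-over-time slope for one electrode
#'
#' Ordinary least-squares fit of SPPR against day, restricted to
#' construct-on timepoints. The fit is refused — an explicit refusal object,
#' not a numeric zero — when fewer than `min_points` construct-on
#' timepoints are available or when no included timepoint lies beyond
#' `min_beyond_day` (the bulk-resistance inflection), because a slope fitted
#' before the trajectory turns is not interpretable as a progression rate.
#'
#' @param series A [marker_series()].
#' @param min_points Minimum number of included timepoints (default 3).
#' @param min_beyond_day At least one included day must exceed this
#'   (default 7).
#' @return A list of class `sppr_slope` with `refused` (logical) and, when
#'   not refused, `slope` (percent/day), `intercept`, `n`, and `final_day`
#'   (the last included day, used to pair the slope with EIS fits).
#' @export
sppr_slope <- function(series, min_points = 3, min_beyond_day = 7) {
  stopifnot(inherits(series, "marker_series"))
  inc <- series[series$construct_on & !is.na(series$sppr_pct), , drop = FALSE]
  if (nrow(inc) < min_points) {
    return(structure(list(refused = TRUE,
                          reason = sprintf("only %d timepoints (need >= %d)",
                                           nrow(inc), min_points)),
                     class = "sppr_slope"))
  }
  if (!any(inc$day > min_beyond_day)) {
    return(structure(list(refused = TRUE,
                          reason = sprintf("no timepoint beyond day %d",
                                           min_beyond_day)),
                     class = "sppr_slope"))
  }
  fit <- stats::lm(sppr_pct ~ day, data = inc)
  structure(list(refused = FALSE,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = nrow(inc),
                 final_day = max(inc$day)),
            class = "sppr_slope")
}

#' Convert implant current levels (CL) to microamps
#'
#' The implant's logarithmic current unit: `uA = 17.5 * 100^(CL / 255)`.
#'
#' @param cl Current level, >= 0 (vectorised).
#' @return Current in microamps.
#' @examples
#' cl_to_microamps(c(0, 255))  # 17.5, 1750
#' @export
cl_to_microamps <- function(cl) {
  if (any(cl < 0)) stop("current level must be non-negative")
  17.5 * 100^(cl / 255)
}

#' Pearson correlation with Fisher-z 95% confidence interval
#'
#' @param x,y Numeric vectors, length >= 4, finite, non-constant.
#' @return A list with `r`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
pearson_ci <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], p_value = ct$p.value, n = length(x))
}
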