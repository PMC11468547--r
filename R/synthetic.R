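#' Configuration for the synthetic fibrosis cohort generator
#'
#' Defines the statistical stand-in for a fibrosing-electrode study:
#' per-electrode baseline circuit elements, logistic (sigmoid) fibrosis
#' trajectories — bulk resistance R1 rising with its inflection between
#' days 7 and 9, bulk capacitance C falling with its inflection between
#' days 4 and 7, interface CPE and series R2 constant — plus measurement
#' noise for EIS sweeps and waveform repeats. A fraction of electrodes has
#' the construct contract off at a late day, after which parameters revert
#' to baseline.
#'
#' The R1 and C fold-changes of an electrode are coupled through a shared
#' latent severity factor: stronger fibrosis raises R1 more and depresses C
#' more, as both are driven by the same matrix-contraction process.
#'
#' @param n_electrodes Number of electrodes in the cohort.
#' @param days Measurement days (default 2, 4, 7, 9, 11, 14).
#' @param y_range,p_range,r1_range,c_range,r2_range Uniform baseline ranges
#'   for CPE-T (S·s^p), CPE-P, R1 (ohm), C (F), R2 (ohm).
#' @param r1_fold_range Multiplicative R1 rise by day 14 (default 2-6).
#' @param r1_inflection_range Day window for the R1 inflection (default 7-9).
#' @param c_fold_range Divisive C fall by day 14 (default 2-10).
#' @param c_inflection_range Day window for the C inflection (default 4-7).
#' @param trajectory_width Logistic time constant, days.
#' @param construct_off_fraction Fraction of electrodes whose construct
#'   contracts off; the off day is drawn from the days beyond day 7.
#' @param eis_mag_noise Log-normal multiplicative magnitude noise (sdlog).
#' @param eis_phase_noise Gaussian phase noise, degrees.
#' @param n_eis_repeats Sweeps per electrode and timepoint.
#' @param wf_noise_sd Additive Gaussian waveform noise, volt.
#' @param wf_offset_sd Per-repeat constant baseline offset SD, volt.
#' @param n_wf_repeats Waveform repeats per electrode and timepoint.
#' @param wf_sampling_rate Raw acquisition rate, Hz (125 MHz: decimation by
#'   20 gives 6.25 MHz, on which 500 samples span exactly 80 us).
#' @param pre_stimulus_s Pre-stimulus record length, seconds.
#' @param record_s Post-onset record length, seconds.
#' @param seed Mandatory integer seed; all cohort randomness flows from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_electrodes = 30L,
                          days = c(2L, 4L, 7L, 9L, 11L, 14L),
                          y_range = c(1e-6, 1.6e-6),
                          p_range = c(0.75, 0.85),
                          r1_range = c(25, 200),
                          c_range = c(5e-9, 3e-8),
                          r2_range = c(100, 200),
                          r1_fold_range = c(2, 6),
                          r1_inflection_range = c(7, 9),
                          c_fold_range = c(2, 10),
                          c_inflection_range = c(4, 7),
                          trajectory_width = 1.2,
                          construct_off_fraction = 0.2,
                          eis_mag_noise = 0.02,
                          eis_phase_noise = 1,
                          n_eis_repeats = 3L,
                          wf_noise_sd = 1e-2,
                          wf_offset_sd = 2e-3,
                          n_wf_repeats = 15L,
                          wf_sampling_rate = 125e6,
                          pre_stimulus_s = 1e-4,
                          record_s = 3e-4,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_electrodes >= 1, !is.unsorted(days, strictly = TRUE),
            all(r1_fold_range > 1), all(c_fold_range > 1),
            eis_mag_noise >= 0, eis_phase_noise >= 0,
            construct_off_fraction >= 0, construct_off_fraction <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

logistic <- function(x) 1 / (1 + exp(-x))

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a synthetic fibrosis cohort
#'
#' Draws per-electrode baselines and trajectory shapes, evaluates the
#' ground-truth circuit parameters at every measurement day, and generates
#' noisy EIS recordings. Raw waveform repeats are regenerated on demand via
#' [cohort_waveforms()] from per-electrode/day seeds stored here, so the
#' full ground truth travels with every measurement without holding the
#' (large) raw traces in memory.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: `config`, `truth` (data
#'   frame of per-electrode/day parameters and construct flags) and
#'   `electrodes` (per-electrode list with `eis` recordings and waveform
#'   seeds).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  electrodes <- vector("list", config$n_electrodes)
  truth_rows <- list()
  off_days <- config$days[config$days > 7]
  for (e in seq_len(config$n_electrodes)) {
    id <- sprintf("E%02d", e)
    y <- runif1(config$y_range)
    p <- runif1(config$p_range)
    r1_0 <- runif1(config$r1_range)
    c_0 <- runif1(config$c_range)
    r2 <- runif1(config$r2_range)
    sev <- stats::runif(1)
    jig <- function() min(max(sev + stats::rnorm(1, 0, 0.1), 0), 1)
    r1_fold <- config$r1_fold_range[1] + jig() * diff(config$r1_fold_range)
    c_fold <- config$c_fold_range[1] + jig() * diff(config$c_fold_range)
    d_r1 <- runif1(config$r1_inflection_range)
    d_c <- runif1(config$c_inflection_range)
    off_day <- if (length(off_days) && stats::runif(1) < config$construct_off_fraction) {
      off_days[sample.int(length(off_days), 1)]
    } else NA_integer_

    params_by_day <- list()
    eis <- list()
    wf_seeds <- integer(length(config$days))
    for (j in seq_along(config$days)) {
      day <- config$days[j]
      on <- is.na(off_day) || day < off_day
      if (on) {
        r1 <- r1_0 * (1 + (r1_fold - 1) *
                        logistic((day - d_r1) / config$trajectory_width))
        cc <- c_0 / (1 + (c_fold - 1) *
                       logistic((day - d_c) / config$trajectory_width))
      } else {
        r1 <- r1_0
        cc <- c_0
      }
      pars <- circuit_params(y, p, r1, cc, r2)
      params_by_day[[j]] <- pars
      eis[[j]] <- synth_eis(pars,
                            noise = list(mag = config$eis_mag_noise,
                                         phase_deg = config$eis_phase_noise),
                            n_repeats = config$n_eis_repeats,
                            electrode_id = id, day = day, construct_on = on)
      wf_seeds[j] <- sample.int(.Machine$integer.max, 1)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        electrode_id = id, day = day, construct_on = on,
        cpe_t = y, cpe_p = p, r1 = r1, c = cc, r2 = r2)
    }
    electrodes[[e]] <- list(electrode_id = id, construct_off_day = off_day,
                            params = params_by_day, eis = eis,
                            wf_seeds = wf_seeds)
  }
  structure(list(config = config,
                 truth = do.call(rbind, truth_rows),
                 electrodes = electrodes),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$electrodes), " electrodes x ",
      length(x$config$days), " days (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Raw waveform repeats for one electrode/day of a cohort
#'
#' Regenerates the raw waveform set deterministically from the seed stored
#' at cohort creation.
#'
#' @param cohort A [make_cohort()] result.
#' @param electrode Electrode index (1-based).
#' @param day_index Index into `cohort$config$days`.
#' @param pulse The stimulating [pulse_spec()].
#' @return A [raw_waveform_set()].
#' @export
cohort_waveforms <- function(cohort, electrode, day_index, pulse) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  el <- cohort$electrodes[[electrode]]
  cfg <- cohort$config
  synth_waveforms(el$params[[day_index]], pulse,
                  noise = list(sd = cfg$wf_noise_sd,
                               offset_sd = cfg$wf_offset_sd),
                  n_repeats = cfg$n_wf_repeats,
                  sampling_rate = cfg$wf_sampling_rate,
                  pre_stimulus_s = cfg$pre_stimulus_s,
                  record_s = cfg$record_s,
                  seed = el$wf_seeds[day_index])
}

#' Synthesise a noisy EIS recording from known circuit parameters
#'
#' Evaluates the circuit on the standard 41-point sweep and applies
#' independent log-normal multiplicative noise to the magnitude and
#' Gaussian noise to the phase, per repeat. Phases are clipped to the valid
#' (-90, 90] degree range.
#'
#' @param params A [circuit_params()].
#' @param noise List with `mag` (sdlog of the multiplicative magnitude
#'   noise, default 0.02) and `phase_deg` (phase noise SD, default 1).
#' @param n_repeats Number of repeats (default 3).
#' @param frequencies Sweep grid, Hz.
#' @param electrode_id,day,construct_on Recording metadata.
#' @param seed Optional seed; when NULL the current RNG stream is used
#'   (as inside [make_cohort()]).
#' @return An [eis_recording()].
#' @export
synth_eis <- function(params, noise = list(mag = 0.02, phase_deg = 1),
                      n_repeats = 3L, frequencies = eis_frequency_grid(),
                      electrode_id = "E01", day = 0L, construct_on = TRUE,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise$mag >= 0, noise$phase_deg >= 0)
  z <- circuit_impedance(params, frequencies)
  mag0 <- Mod(z)
  ph0 <- Arg(z) * 180 / pi
  reps <- lapply(seq_len(n_repeats), function(i) {
    mag <- mag0 * exp(stats::rnorm(length(mag0), 0, noise$mag))
    ph <- ph0 + stats::rnorm(length(ph0), 0, noise$phase_deg)
    ph <- pmin(pmax(ph, -89.99), 90)
    impedance_spectrum(frequencies, mag, ph)
  })
  eis_recording(electrode_id, day, reps, construct_on)
}

#' Synthesise raw waveform repeats from known circuit parameters
#'
#' Embeds the closed-form pulse response after a pre-stimulus segment and
#' adds, per repeat, white Gaussian noise plus a constant baseline offset
#' (emulating environmental pickup).
#'
#' @param params A [circuit_params()].
#' @param pulse A [pulse_spec()].
#' @param noise List with `sd` (additive noise SD, volt) and `offset_sd`
#'   (per-repeat constant offset SD, volt).
#' @param n_repeats Number of repeats (default 15).
#' @param sampling_rate Raw sampling rate, Hz; must resolve the phase
#'   duration with at least 100 samples.
#' @param pre_stimulus_s Pre-stimulus duration, seconds (>= 80 us so the
#'   standard baseline window fits).
#' @param record_s Post-onset duration, seconds.
#' @param seed Optional seed; NULL uses the current RNG stream.
#' @return A [raw_waveform_set()].
#' @export
synth_waveforms <- function(params, pulse,
                            noise = list(sd = 1e-2, offset_sd = 2e-3),
                            n_repeats = 15L, sampling_rate = 125e6,
                            pre_stimulus_s = 1e-4, record_s = 3e-4,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sampling_rate * pulse$t0 < 100) {
    stop("sampling rate must resolve the phase duration with >= 100 samples")
  }
  if (pre_stimulus_s < 80e-6) stop("pre-stimulus segment must cover >= 80 us")
  n_pre <- round(pre_stimulus_s * sampling_rate)
  n_tot <- n_pre + round(record_s * sampling_rate)
  times <- (seq_len(n_tot) - 1 - n_pre) / sampling_rate
  v <- simulate_waveform(params, pulse, times)$mean_v
  reps <- matrix(0, n_tot, n_repeats)
  for (r in seq_len(n_repeats)) {
    reps[, r] <- v + stats::rnorm(n_tot, 0, noise$sd) +
      stats::rnorm(1, 0, noise$offset_sd)
  }
  raw_waveform_set(sampling_rate, reps, pre_stimulus_samples = n_pre)
}

#' Degenerate EIS recordings for QC-rule fixtures
#'
#' Each kind is constructed to trip exactly one exclusion rule of
#' [qc_screen()] at default settings:
#' `"open_circuit"` — a near-open interface (tiny CPE magnitude) whose
#' 10 Hz magnitude far exceeds 50 kOhm (rule R2);
#' `"air_bubble"` — a flat, near-resistive spectrum with phase around -5
#' degrees across the low band (rule R3);
#' `"noisy_phase"` — a healthy circuit with 8-degree phase noise so the
#' upper-quartile phase SD exceeds 4 degrees (rule R1).
#'
#' @param kind One of `"open_circuit"`, `"air_bubble"`, `"noisy_phase"`.
#' @param seed Optional seed; NULL uses the current RNG stream.
#' @param frequencies Sweep grid, Hz.
#' @return An [eis_recording()] with three repeats.
#' @export
degenerate_recording <- function(kind = c("open_circuit", "air_bubble",
                                          "noisy_phase"),
                                 seed = NULL,
                                 frequencies = eis_frequency_grid()) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  id <- paste0("degenerate-", kind)
  base <- circuit_params(2e-6, 0.8, 500, 5e-9, 250)
  switch(kind,
    open_circuit = synth_eis(circuit_params(2e-8, 0.8, 500, 5e-9, 250),
                             noise = list(mag = 0.01, phase_deg = 0.3),
                             electrode_id = id),
    air_bubble = {
      reps <- lapply(1:3, function(i) {
        mag <- 1e4 * exp(stats::rnorm(length(frequencies), 0, 0.01))
        ph <- pmin(stats::rnorm(length(frequencies), -5, 0.3), -0.1)
        impedance_spectrum(frequencies, mag, ph)
      })
      eis_recording(id, 0L, reps)
    },
    noisy_phase = synth_eis(base,
                            noise = list(mag = 0.02, phase_deg = 8),
                            electrode_id = id)
  )
}
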