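#' Raw waveform repeats for one electrode, timepoint and polarity
#'
#' @param sampling_rate Acquisition sampling rate, Hz.
#' @param repeats Numeric matrix of voltage traces, one column per repeat
#'   (volt), all the same length.
#' @param pre_stimulus_samples Number of samples recorded before pulse onset.
#' @return An object of class `raw_waveform_set`.
#' @export
raw_waveform_set <- function(sampling_rate, repeats, pre_stimulus_samples) {
  repeats <- as.matrix(repeats)
  stopifnot(sampling_rate > 0, nrow(repeats) >= 2,
            pre_stimulus_samples >= 0,
            pre_stimulus_samples < nrow(repeats))
  structure(list(sampling_rate = sampling_rate, repeats = repeats,
                 pre_stimulus_samples = as.integer(pre_stimulus_samples)),
            class = "raw_waveform_set")
}

#' Filter, decimate and baseline-correct raw waveform repeats
#'
#' Per repeat: first-order digital Butterworth low-pass at `cutoff_hz`
#' (one-pass, causal), decimation by plain sample-picking (the Butterworth
#' filter is the anti-alias step), then subtraction of the mean of the
#' first `baseline_samples` output samples — a window that must lie
#' entirely before pulse onset. Mean and standard deviation are then taken
#' across repeats.
#'
#' Defaults reproduce the acquisition pipeline this package models: 80 kHz
#' cutoff, decimation by 20, and a 500-sample baseline window (80 us at the
#' decimated 6.25 MHz rate).
#'
#' @param raw A [raw_waveform_set()].
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @param downsample_factor Integer decimation factor, >= 1.
#' @param baseline_samples Number of leading output samples used for the
#'   baseline (offset) estimate.
#' @return A [voltage_waveform()] at `sampling_rate / downsample_factor`,
#'   with `onset_time` set from the recorded pre-stimulus sample count.
#' @export
preprocess <- function(raw, cutoff_hz = 80e3, downsample_factor = 20L,
                       baseline_samples = 500L) {
  stopifnot(inherits(raw, "raw_waveform_set"))
  downsample_factor <- as.integer(downsample_factor)
  stopifnot(downsample_factor >= 1, baseline_samples >= 1)
  fs <- raw$sampling_rate
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (baseline_samples * downsample_factor > raw$pre_stimulus_samples) {
    stop("baseline window overlaps the stimulus: need ",
         baseline_samples * downsample_factor,
         " pre-stimulus samples, have ", raw$pre_stimulus_samples)
  }
  n_in <- nrow(raw$repeats)
  if (n_in %% downsample_factor != 0) {
    warning("input length not a multiple of the decimation factor; truncating")
  }
  bf <- signal::butter(1, cutoff_hz / (fs / 2), type = "low")
  pick <- seq(1L, n_in, by = downsample_factor)
  out <- apply(raw$repeats, 2, function(x) {
    # reference the filter to the trace's initial value so a constant
    # (environmental) offset passes without a start-up transient and is
    # then removed exactly by the baseline correction
    y <- (signal::filter(bf, x - x[1]) + x[1])[pick]
    y - mean(y[seq_len(baseline_samples)])
  })
  fs_out <- fs / downsample_factor
  times <- (pick - 1L) / fs
  voltage_waveform(
    times = times,
    mean_v = rowMeans(out),
    std_v = if (ncol(out) >= 2) apply(out, 1, stats::sd) else NULL,
    sampling_rate = fs_out,
    onset_time = raw$pre_stimulus_samples / fs
  )
}

#' Detect pulse onset as an RMS-level change point
#'
#' Finds the single split of the mean trace into two segments that
#' minimises the pooled Gaussian (zero-mean, per-segment variance) cost —
#' the standard single change point in root-mean-square level. The detected
#' onset is the first sample of the second segment.
#'
#' The change must rise above the noise floor: the post-onset absolute peak
#' has to exceed 3 times the pre-onset standard deviation, otherwise the
#' trace is declared flat and an error is raised.
#'
#' @param waveform A [voltage_waveform()] containing a pre-stimulus segment.
#' @return Onset time, seconds (on the waveform's time grid).
#' @export
detect_onset <- function(waveform) {
  stopifnot(inherits(waveform, "voltage_waveform"))
  x <- waveform$mean_v
  n <- length(x)
  if (n < 8) stop("waveform too short for change-point detection")
  cs <- cumsum(x^2)
  # the onset must precede the absolute peak; restricting the split there
  # stops the search from latching onto the pulse-to-tail transition
  k_max <- max(which.max(abs(x)) - 1L, 3L)
  k <- 2:min(k_max, n - 2)  # >= 2 samples in each segment
  m1 <- pmax(cs[k] / k, .Machine$double.xmin)
  m2 <- pmax((cs[n] - cs[k]) / (n - k), .Machine$double.xmin)
  cost <- k * log(m1) + (n - k) * log(m2)
  kbest <- k[which.min(cost)]
  pre_sd <- stats::sd(x[seq_len(kbest)])
  post_peak <- max(abs(x[(kbest + 1):n]))
  if (!is.finite(pre_sd) || post_peak <= 3 * pre_sd || post_peak == 0) {
    stop("no onset detected")
  }
  waveform$times[kbest + 1]
}

#' Set (or re-detect) the onset of a waveform
#'
#' @param waveform A [voltage_waveform()].
#' @param onset_time Onset in seconds; when NULL, [detect_onset()] is used.
#' @return The waveform with `onset_time` filled in.
#' @export
align_waveform <- function(waveform, onset_time = NULL) {
  waveform$onset_time <- if (is.null(onset_time)) detect_onset(waveform) else onset_time
  waveform
}
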