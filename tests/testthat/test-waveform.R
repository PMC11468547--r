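test_that("biphasic current is charge balanced and has the right phases", {
  dt <- 1e-7
  times <- seq(-20e-6, 300e-6, by = dt)
  # sampled charge balance, allowing one boundary sample of float jitter
  for (gap in c(0, 9e-6)) {
    for (pol in c("cathodic", "anodic")) {
      pu <- pulse_spec(50e-6, 50e-6, gap = gap, polarity = pol)
      i <- biphasic_current(pu, times)
      expect_lte(abs(sum(i)), 1.5 * pu$i_amp)
    }
  }
  pu <- pulse_spec(50e-6, 50e-6)
  i <- biphasic_current(pu, times)
  mid <- function(a, b) times > a + dt / 2 & times < b - dt / 2
  expect_equal(unique(i[mid(0, 50e-6)]), -50e-6)
  expect_equal(unique(i[mid(50e-6, 100e-6)]), 50e-6)
  expect_equal(unique(i[times > 100e-6 + dt / 2]), 0)
  # the telemetry pulse: 25 us phases, 9 us gap -> support ends at 59 us
  pt <- pulse_spec(125e-6, 25e-6, gap = 9e-6)
  ip <- biphasic_current(pt, times)
  expect_equal(max(times[ip != 0]), 59e-6, tolerance = 2 * dt)
  expect_true(all(ip[times >= 59e-6 + dt / 2] == 0))
  expect_error(biphasic_current(pu, c(0, 1e-6, 3e-6)), "uniform")
})

test_that("pulse spec enforces its invariants", {
  expect_error(pulse_spec(0, 50e-6))
  expect_error(pulse_spec(50e-6, 0))
  expect_error(pulse_spec(50e-6, 50e-6, gap = -1e-6))
})

test_that("simulated waveform starts at -i_amp * R2 and decays to zero", {
  p <- default_params()
  pu <- invitro_pulse()
  times <- (-50:25000) * 2e-7  # contains t = 0 exactly; spans 100 * t0
  wf <- simulate_waveform(p, pu, times)
  i0 <- which(times == 0)  # the t = 0 sample (right limit at onset)
  expect_equal(wf$mean_v[i0], -pu$i_amp * p$r2, tolerance = 1e-12)
  expect_true(all(wf$mean_v[times < 0] == 0))
  peak <- max(abs(wf$mean_v))
  expect_lt(abs(wf$mean_v[length(times)]), 0.01 * peak)
})

test_that("simulated waveform is linear in amplitude and odd in polarity", {
  p <- default_params()
  times <- dense_times()
  v1 <- simulate_waveform(p, pulse_spec(50e-6, 50e-6), times)$mean_v
  v2 <- simulate_waveform(p, pulse_spec(100e-6, 50e-6), times)$mean_v
  expect_equal(v2, 2 * v1, tolerance = 1e-14)
  va <- simulate_waveform(p, pulse_spec(50e-6, 50e-6, polarity = "anodic"),
                          times)$mean_v
  expect_equal(va, -v1, tolerance = 1e-14)
})

test_that("closed form matches the numerical inversion oracle", {
  pu <- invitro_pulse()
  dt <- 1.6e-7
  times <- seq(-10e-6, 300e-6, by = dt)
  switch_times <- c(0, pu$t0, 2 * pu$t0)
  keep <- !Reduce(`|`, lapply(switch_times,
                              function(s) abs(times - s) <= 2 * dt))
  for (p_exp in c(0.7, 0.85, 1)) {
    p <- circuit_params(1e-7, p_exp, 500, 1e-9, 300)
    v <- simulate_waveform(p, pu, times)$mean_v
    v_num <- simulate_waveform_numeric(p, pu, times)$mean_v
    expect_lt(max(abs(v - v_num)[keep]) / max(abs(v)), 1e-3)
  }
})

test_that("p = 1 reduces to the textbook R + C + R||C response", {
  c0 <- 2e-7
  p <- circuit_params(c0, 1, 500, 1e-9, 300)
  pu <- invitro_pulse()
  times <- dense_times()
  v <- simulate_waveform(p, pu, times)$mean_v
  # independent textbook superposition: ideal-capacitor ramp t/C0 plus
  # RC charging plus resistive step, per current step of the stimulus
  r_text <- function(t) ifelse(t >= 0, t / c0 +
                                 500 * (1 - exp(-t / (500 * 1e-9))) + 300, 0)
  v_text <- -pu$i_amp * (r_text(times) - 2 * r_text(times - pu$t0) +
                           r_text(times - 2 * pu$t0))
  expect_lt(max(abs(v - v_text)) / max(abs(v_text)), 1e-6)
})

test_that("waveforms with an interphase gap superpose four step responses", {
  p <- default_params()
  pu <- pulse_spec(125e-6, 25e-6, gap = 9e-6)
  times <- seq(-10e-6, 200e-6, by = 1e-7)
  v <- simulate_waveform(p, pu, times)$mean_v
  # during the gap the current is zero; voltage must be decaying, not stepping
  in_gap <- times > 25e-6 + 2e-7 & times < 34e-6 - 2e-7
  expect_true(all(abs(diff(v[in_gap])) < 0.02 * max(abs(v))))
  # charge balance still holds (one boundary sample of float jitter allowed)
  i <- biphasic_current(pu, times)
  expect_lte(abs(sum(i)), 1.5 * pu$i_amp)
})

test_that("onset detection finds the embedded pulse", {
  p <- regime_params()
  pu <- invitro_pulse()
  fs <- 6.25e6
  n_pre <- 500
  times <- (seq_len(3000) - 1 - n_pre) / fs
  v <- simulate_waveform(p, pu, times)$mean_v
  wf <- voltage_waveform(times, v, sampling_rate = fs)
  expect_equal(detect_onset(wf), 0, tolerance = 1 / fs)

  set.seed(108)
  hits <- 0
  for (s in 1:20) {
    vn <- v + rnorm(length(v), 0, 0.01 * max(abs(v)))
    wfn <- voltage_waveform(times, vn, sampling_rate = fs)
    t_on <- tryCatch(detect_onset(wfn), error = function(e) NA)
    if (!is.na(t_on) && abs(t_on) <= 2 / fs) hits <- hits + 1
  }
  expect_gte(hits, 19)

  flat <- voltage_waveform(times, numeric(length(times)), sampling_rate = fs)
  expect_error(detect_onset(flat), "no onset")
})

test_that("preprocessing filters, decimates and removes the baseline", {
  p <- regime_params()
  pu <- invitro_pulse()
  raw <- synth_waveforms(p, pu, noise = list(sd = 0, offset_sd = 5e-3),
                         n_repeats = 3, seed = 11)
  wf <- preprocess(raw)
  expect_equal(length(wf$times), floor(nrow(raw$repeats) / 20))
  expect_equal(wf$sampling_rate, raw$sampling_rate / 20)
  # constant per-repeat offsets vanish with the baseline correction
  pre <- wf$times < wf$onset_time - 5e-6
  expect_lt(abs(mean(wf$mean_v[pre])), 1e-12)
  # away from switching transients the filtered waveform tracks the closed form
  truth <- simulate_waveform(p, pu, wf$times - wf$onset_time)$mean_v
  switch_times <- wf$onset_time + c(0, pu$t0, 2 * pu$t0)
  settled <- !Reduce(`|`, lapply(switch_times,
                                 function(s) wf$times >= s - 2e-6 & wf$times <= s + 20e-6))
  # the causal first-order filter tracks the CPE ramp with a constant lag
  # (~ 1/(2 pi fc) times the local slope), bounding agreement at the
  # percent level rather than at numerical precision
  expect_lt(max(abs(wf$mean_v - truth)[settled]) / max(abs(truth)), 0.03)
})

test_that("the preprocessing filter is -3 dB at its cutoff", {
  fs <- 125e6
  bf <- signal::butter(1, 80e3 / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * 80e3 / fs)
  h <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  expect_equal(Mod(h), 1 / sqrt(2), tolerance = 1e-9)
})

test_that("preprocess rejects a baseline window that overlaps the stimulus", {
  p <- regime_params()
  raw <- synth_waveforms(p, invitro_pulse(), noise = list(sd = 0, offset_sd = 0),
                         n_repeats = 2, pre_stimulus_s = 85e-6, seed = 3)
  # 600 output samples * factor 20 = 12000 raw samples > 85 us * 125 MHz
  expect_error(preprocess(raw, baseline_samples = 600), "overlaps")
})
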