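aligned_sim <- function(params = default_params(), pulse = invitro_pulse(),
                        times = seq(-5e-6, 150e-6, by = 2e-8)) {
  simulate_waveform(params, pulse, times)  # onset_time = 0 by construction
}

# closed-form phase-end voltages of the circuit (right limits at T0- / 2T0-)
closed_form_peaks <- function(p, pu) {
  k <- pu$t0^p$cpe_p / (p$cpe_t * gamma(p$cpe_p + 1))
  a <- pu$t0 / (p$r1 * p$c)
  z1 <- k + p$r1 * (1 - exp(-a)) + p$r2
  z2 <- (2 - 2^p$cpe_p) * k + p$r1 * (1 - exp(-a))^2 + p$r2
  list(first = pu$i_amp * z1, second = pu$i_amp * z2)
}

test_that("contact impedance is first-phase peak over input current", {
  # hand-built waveform: 5 mV peak in the first phase at 50 uA -> 100 Ohm
  fs <- 6.25e6
  times <- (0:999) / fs
  v <- numeric(1000)
  v[times < 50e-6] <- -5e-3 * sin(pi * times[times < 50e-6] / 50e-6)
  wf <- voltage_waveform(times, v, sampling_rate = fs, onset_time = 0)
  expect_equal(contact_impedance(wf, invitro_pulse()), 100, tolerance = 1e-4)
})

test_that("contact impedance of a simulated waveform matches the closed form", {
  p <- default_params()
  pu <- invitro_pulse()
  wf <- aligned_sim(p, pu)
  cf <- closed_form_peaks(p, pu)
  expect_lt(rel_err(contact_impedance(wf, pu), cf$first / pu$i_amp), 1e-3)
  # invariant to the stimulus amplitude
  pu2 <- pulse_spec(100e-6, 50e-6)
  expect_equal(contact_impedance(aligned_sim(p, pu2), pu2),
               contact_impedance(wf, pu), tolerance = 1e-12)
})

test_that("marker extraction demands an aligned waveform inside the record", {
  wf <- aligned_sim()
  wf$onset_time <- NA_real_
  expect_error(contact_impedance(wf, invitro_pulse()), "aligned")
  wf2 <- aligned_sim()
  wf2$onset_time <- 1  # window beyond the record
  expect_error(contact_impedance(wf2, invitro_pulse()), "outside")
})

test_that("SPPR is 100% for a mirror-symmetric biphasic response", {
  fs <- 6.25e6
  times <- (0:999) / fs
  v <- numeric(1000)
  ph1 <- times < 50e-6
  ph2 <- times >= 50e-6 & times < 100e-6
  v[ph1] <- -3e-3 * sin(pi * times[ph1] / 50e-6)
  v[ph2] <- 3e-3 * sin(pi * (times[ph2] - 50e-6) / 50e-6)
  wf <- voltage_waveform(times, v, sampling_rate = fs, onset_time = 0)
  expect_equal(sppr(wf, invitro_pulse()), 100, tolerance = 1e-9)
})

test_that("SPPR of a simulated waveform matches the closed-form ratio", {
  p <- default_params()
  pu <- invitro_pulse()
  cf <- closed_form_peaks(p, pu)
  expect_lt(rel_err(sppr(aligned_sim(p, pu), pu), 100 * cf$second / cf$first),
            2e-3)
})

test_that("SPPR is polarity- and amplitude-invariant", {
  p <- default_params()
  pu <- invitro_pulse()
  s0 <- sppr(aligned_sim(p, pu), pu)
  pu_a <- pulse_spec(50e-6, 50e-6, polarity = "anodic")
  expect_equal(sppr(aligned_sim(p, pu_a), pu_a), s0, tolerance = 1e-12)
  pu_2x <- pulse_spec(100e-6, 50e-6)
  expect_equal(sppr(aligned_sim(p, pu_2x), pu_2x), s0, tolerance = 1e-12)
})

test_that("SPPR rises as bulk capacitance falls and as bulk resistance rises", {
  pu <- invitro_pulse()
  c_grid <- 10^seq(-10, -6, length.out = 9)
  s_c <- vapply(c_grid, function(cc) {
    sppr(aligned_sim(circuit_params(1e-7, 0.8, 500, cc, 300), pu), pu)
  }, numeric(1))
  expect_true(all(diff(s_c) <= 1e-9))
  expect_lt(s_c[length(s_c)], 100)
  # R1 sweep at the operating point C = 1 nF (bulk discharges within the
  # phase, R1*C << T0 — the regime where the marker mechanism is valid)
  r_grid <- seq(100, 2000, length.out = 9)
  s_r <- vapply(r_grid, function(r1) {
    sppr(aligned_sim(circuit_params(1e-7, 0.8, r1, 1e-9, 300), pu), pu)
  }, numeric(1))
  expect_true(all(diff(s_r) >= -1e-9))
})

test_that("patient telemetry markers follow the clinical definitions", {
  tel <- patient_telemetry(
    "P1", 5, "3 months",
    phase1 = data.frame(offset_us = c(6, 25), voltage_v = c(-0.8, -1.25)),
    phase2 = data.frame(offset_us = c(6, 25), voltage_v = c(0.8, 1.1)),
    input_current = 125e-6)
  expect_equal(altered_sppr(tel), 100)
  expect_equal(patient_contact_impedance(tel), 1.25 / 125e-6)
  # intraoperative currents scale the impedance down
  tel_intra <- patient_telemetry("P1", 5, "intraoperative",
                                 tel$phase1, tel$phase2,
                                 input_current = 435e-6)
  expect_equal(patient_contact_impedance(tel_intra) /
                 patient_contact_impedance(tel), 125 / 435, tolerance = 1e-12)
  # missing offsets and zero denominators are refused
  expect_error(altered_sppr(tel, offset_us = 7), "no phase-1 sample")
  tel0 <- tel
  tel0$phase1$voltage_v <- c(0, -1.25)
  expect_error(altered_sppr(tel0), "zero phase-1")
})

test_that("telemetry markers agree with dense gapped-pulse simulation", {
  p <- default_params()
  pu <- pulse_spec(125e-6, 25e-6, gap = 9e-6)
  dt <- 1e-7
  times <- seq(-5e-6, 120e-6, by = dt)
  v <- simulate_waveform(p, pu, times)$mean_v
  at <- function(t_us) v[which.min(abs(times - t_us * 1e-6))]
  tel <- patient_telemetry(
    "P1", 1, "3 months",
    phase1 = data.frame(offset_us = c(6, 25),
                        voltage_v = c(at(6), at(25))),
    phase2 = data.frame(offset_us = c(6, 25),
                        voltage_v = c(at(25 + 9 + 6), at(25 + 9 + 25))),
    input_current = pu$i_amp)
  expect_equal(altered_sppr(tel), 100 * abs(at(40)) / abs(at(6)),
               tolerance = 1e-12)
  expect_equal(patient_contact_impedance(tel), abs(at(25)) / pu$i_amp,
               tolerance = 1e-12)
})

test_that("marker series normalisation is exact and idempotent", {
  ms <- marker_series("E01", c(2, 7, 14), c(200, 300, 500), c(60, 70, 90))
  n1 <- normalize_series(ms)
  expect_equal(n1$rel_contact_impedance, c(1, 1.5, 2.5))
  expect_equal(n1$rel_sppr[1], 1)
  expect_identical(normalize_series(n1), n1)
  const <- normalize_series(marker_series("E02", c(2, 4), c(5, 5), c(50, 50)))
  expect_equal(const$rel_contact_impedance, c(1, 1))
  expect_error(normalize_series(ms, baseline_day = 3), "baseline")
})

test_that("SPPR slope fitting applies the inclusion rules", {
  refuse1 <- sppr_slope(marker_series("E", c(2, 4), c(1, 1), c(50, 55)))
  expect_true(refuse1$refused)
  refuse2 <- sppr_slope(marker_series("E", c(2, 4, 7), rep(1, 3), c(50, 55, 60)))
  expect_true(refuse2$refused)
  days <- c(2, 4, 7, 9, 11, 14)
  exact <- sppr_slope(marker_series("E", days, rep(1, 6), 40 + 2 * days))
  expect_false(exact$refused)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$final_day, 14)
  # construct-off timepoints are excluded from the fit
  mixed <- sppr_slope(marker_series("E", days, rep(1, 6), 40 + 2 * days,
                                    construct_on = c(rep(TRUE, 4), FALSE, FALSE)))
  expect_equal(mixed$final_day, 9)
  expect_equal(mixed$n, 4)
})

test_that("current-level conversion matches the device formula", {
  expect_equal(cl_to_microamps(0), 17.5)
  expect_equal(cl_to_microamps(255), 1750)
  cls <- seq(0, 255, by = 5)
  expect_true(all(diff(cl_to_microamps(cls)) > 0))
  expect_error(cl_to_microamps(-1), "non-negative")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_ci(x, x)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)
  expect_error(pearson_ci(x, rep(1, 10)), "variance")
  expect_error(pearson_ci(1:3, 1:3))
})

test_that("the Fisher-z interval covers zero about 95% of the time", {
  set.seed(109)
  covered <- 0
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    x <- rnorm(33)
    y <- rnorm(33)
    ci <- pearson_ci(x, y)
    if (ci$ci_low <= 0 && ci$ci_high >= 0) covered <- covered + 1
  }
  expect_gt(covered / n_sim, 0.9)
  expect_lt(covered / n_sim, 0.99)
})
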