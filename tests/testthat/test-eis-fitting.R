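make_recording <- function(params = regime_params(), noise_mag = 0.005,
                           noise_phase = 0.2, seed = 1, day = 2,
                           id = "E01") {
  synth_eis(params, noise = list(mag = noise_mag, phase_deg = noise_phase),
            electrode_id = id, day = day, seed = seed)
}

test_that("clean recordings pass the QC screen", {
  qc <- qc_screen(make_recording())
  expect_true(qc$keep)
  expect_equal(nrow(qc$reasons), 0)
})

test_that("high 10 Hz magnitude triggers rule R2", {
  f <- eis_frequency_grid()
  reps <- lapply(1:3, function(i) {
    impedance_spectrum(f, exp(seq(log(60e3), log(500), length.out = 41)),
                       rep(-70, 41))
  })
  qc <- qc_screen(eis_recording("E01", 2, reps))
  expect_false(qc$keep)
  expect_true("R2" %in% qc$reasons$rule)
  expect_false("R3" %in% qc$reasons$rule)
})

test_that("shallow phase in the low band triggers rule R3, open interval", {
  f <- eis_frequency_grid()
  shallow <- function(ph_at_100) {
    ph <- rep(-70, 41)
    ph[abs(f - 100) < 1] <- ph_at_100
    reps <- lapply(1:3, function(i) {
      impedance_spectrum(f, exp(seq(log(2e4), log(500), length.out = 41)), ph)
    })
    qc_screen(eis_recording("E01", 2, reps))
  }
  qc <- shallow(-10)
  expect_false(qc$keep)
  expect_equal(qc$reasons$rule, "R3")
  # boundary values do not trigger: the interval is open
  expect_true(shallow(-20)$keep)
})

test_that("unstable phase across repeats triggers rule R1", {
  qc <- qc_screen(degenerate_recording("noisy_phase", seed = 5))
  expect_false(qc$keep)
  expect_equal(qc$reasons$rule, "R1")
})

test_that("QC requires at least two repeats", {
  rec <- make_recording()
  rec$repeats <- rec$repeats[1]
  expect_error(qc_screen(rec), "repeats")
})

test_that("weighted ssq is zero for a perfect fit and matches closed forms", {
  p <- regime_params()
  sp <- model_spectrum(p)
  expect_equal(weighted_ssq(sp, p), 0)
  # uniform multiplicative magnitude error, exact phase: each point
  # contributes (0.01/1.01)^2 under data-modulus weighting
  sp2 <- impedance_spectrum(sp$frequencies, sp$z_mag * 1.01, sp$phase_deg)
  expect_equal(weighted_ssq(sp2, p), 100 * (0.01 / 1.01)^2, tolerance = 1e-10)
  expect_equal(weighted_ssq(sp2, p, weighting = "model"), 100 * 0.01^2,
               tolerance = 1e-10)
})

test_that("the simple circuit underfits CPE-generated spectra", {
  set.seed(103)
  for (i in 1:5) {
    p <- random_regime_params()
    sp <- model_spectrum(p)
    full_fit <- fit_spectrum(sp, start_values(sp))
    simple_start <- simple_circuit_params(sp$z_mag[41], sp$z_mag[1],
                                          1 / (2 * pi * 10 * sp$z_mag[1]))
    simple_fit <- fit_spectrum(sp, simple_start)
    expect_gt(simple_fit$weighted_ssq, full_fit$weighted_ssq)
  }
})

test_that("noise-free fits recover all free elements to 0.1%", {
  set.seed(104)
  for (i in 1:5) {
    truth <- random_regime_params()
    sp <- model_spectrum(truth)
    fit <- fit_spectrum(sp, start_values(sp))
    expect_lt(params_rel_err(fit$params, truth), 1e-3)
    expect_lt(fit$weighted_ssq, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("fixed elements are returned bit-for-bit and never improve the fit", {
  truth <- regime_params()
  rec <- make_recording(truth, noise_mag = 0.02, noise_phase = 1, seed = 42)
  m <- mean_spectrum(rec)
  sv <- start_values(m)
  free_fit <- fit_spectrum(m, sv)
  sv_fixed <- sv
  sv_fixed$r2 <- free_fit$params$r2 * 1.07  # deliberately off-optimum
  fixed_fit <- fit_spectrum(m, sv_fixed, fixed_elements = "r2")
  expect_identical(fixed_fit$params$r2, sv_fixed$r2)
  expect_gte(fixed_fit$weighted_ssq, free_fit$weighted_ssq - 1e-12)
  expect_error(fit_spectrum(m, sv, fixed_elements = names(unclass(sv))),
               "all elements fixed")
  expect_error(fit_spectrum(m, sv, fixed_elements = "bogus"), "bogus")
})

test_that("noisy spectra at study noise levels fit below 5%", {
  set.seed(105)
  for (i in 1:5) {
    truth <- random_regime_params()
    m <- mean_spectrum(synth_eis(truth))
    fit <- fit_spectrum(m, start_values(m))
    expect_lt(fit$weighted_ssq, 5)
  }
})

test_that("time-course fitting fixes R2 from the first kept timepoint", {
  set.seed(106)
  days <- c(2L, 4L, 7L, 9L, 11L, 14L)
  base <- circuit_params(1.3e-6, 0.8, 80, 6e-9, 150)
  recs <- lapply(seq_along(days), function(j) {
    d <- days[j]
    p <- circuit_params(base$cpe_t, base$cpe_p,
                        base$r1 * (1 + 4 * plogis((d - 8) / 1.2)),
                        base$c / (1 + 4 * plogis((d - 5.5) / 1.2)),
                        base$r2)
    make_recording(p, noise_mag = 0.01, noise_phase = 0.5, day = d, seed = 200 + j)
  })
  tc <- fit_timecourse(recs)
  r1s <- vapply(tc, function(e) e$fit$params$r1, numeric(1))
  r2s <- vapply(tc, function(e) e$fit$params$r2, numeric(1))
  cs <- vapply(tc, function(e) e$fit$params$c, numeric(1))
  expect_true(all(diff(r1s) > 0))
  expect_true(all(r2s == r2s[1]))  # fixed bit-for-bit after timepoint one
  # late-day true C steps are sub-percent, below fit noise; require the
  # overall decline plus close tracking of the generating trajectory
  c_true <- vapply(seq_along(days), function(j)
    base$c / (1 + 4 * plogis((days[j] - 5.5) / 1.2)), numeric(1))
  expect_lt(cs[6], 0.5 * cs[1])
  expect_lt(max(abs(cs - c_true) / c_true), 0.1)
  expect_identical(tc[[1]]$fit$fixed_elements, character(0))
  expect_identical(tc[[2]]$fit$fixed_elements, "r2")
})

test_that("QC-excluded timepoints leave explicit gaps and warm starts skip them", {
  set.seed(107)
  good <- function(day, seed) make_recording(regime_params(), day = day, seed = seed)
  bad <- degenerate_recording("open_circuit", seed = 9)
  bad$day <- 7L
  recs <- list(good(2, 1), good(4, 2), bad, good(9, 3))
  tc <- fit_timecourse(recs)
  expect_null(tc[[3]]$fit)
  expect_false(tc[[3]]$qc$keep)
  expect_false(is.null(tc[[4]]$fit))
  expect_identical(tc[[4]]$fit$fixed_elements, "r2")
})

test_that("single-timepoint input yields one all-free fit", {
  tc <- fit_timecourse(list(make_recording()))
  expect_length(tc, 1)
  expect_identical(tc[[1]]$fit$fixed_elements, character(0))
})

test_that("a time course with no usable timepoint errors", {
  bad <- degenerate_recording("open_circuit", seed = 10)
  expect_error(fit_timecourse(list(bad)), "QC")
})
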