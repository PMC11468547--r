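# Shared fixtures for the test suite. Everything is generated in code.

default_params <- function() {
  circuit_params(cpe_t = 1e-7, cpe_p = 0.8, r1 = 500, c = 1e-9, r2 = 300)
}

# a mid-range parameter set from the generator's default regime
regime_params <- function() {
  circuit_params(cpe_t = 1.3e-6, cpe_p = 0.8, r1 = 200, c = 5e-9, r2 = 150)
}

invitro_pulse <- function() pulse_spec(i_amp = 50e-6, t0 = 50e-6)

# dense simulated waveform at the decimated acquisition rate (6.25 MHz)
dense_times <- function(t0 = 50e-6, pre = 20e-6, post = 6) {
  dt <- 1.6e-7
  seq(-pre, post * t0, by = dt)
}

# draw a circuit_params from the generator's default baseline ranges
random_regime_params <- function() {
  circuit_params(
    cpe_t = runif(1, 1e-6, 1.6e-6),
    cpe_p = runif(1, 0.75, 0.85),
    r1 = runif(1, 25, 200),
    c = runif(1, 5e-9, 3e-8),
    r2 = runif(1, 100, 200))
}

rel_err <- function(a, b) abs(a - b) / abs(b)

params_rel_err <- function(fit, truth) {
  nm <- names(unclass(truth))
  max(vapply(nm, function(n) rel_err(fit[[n]], truth[[n]]), numeric(1)))
}
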