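#' Configuration for reverse (voltage-waveform) circuit fitting
#'
#' The bulk elements R1 and C are fitted from a voltage waveform while the
#' interface CPE and the series resistor R2 stay fixed at their baseline
#' (day-2) EIS-fitted values. The optimiser is launched from every unique
#' pair of `grid_n` spaced start values per element within the bounds
#' (`grid_n^2` bounded local searches; 900 at the default 30).
#'
#' @param fixed Named list with `cpe_t`, `cpe_p`, `r2`: the elements held
#'   constant during the fit.
#' @param r1_bounds Bounds for R1, ohm (default 50-5000).
#' @param c_bounds Bounds for C, farad (default 1e-13 to 1e-7).
#' @param grid_n Start values per dimension (default 30).
#' @param grid_spacing `"linear"` start spacing on the raw scale (the
#'   default, reproducing the reference procedure even though C spans six
#'   decades) or `"log"`.
#' @return An object of class `vw_fit_config`.
#' @export
vw_fit_config <- function(fixed, r1_bounds = c(50, 5000),
                          c_bounds = c(1e-13, 1e-7), grid_n = 30L,
                          grid_spacing = c("linear", "log")) {
  grid_spacing <- match.arg(grid_spacing)
  stopifnot(is.list(fixed), all(c("cpe_t", "cpe_p", "r2") %in% names(fixed)),
            fixed$cpe_t > 0, fixed$cpe_p > 0, fixed$cpe_p <= 1, fixed$r2 > 0,
            length(r1_bounds) == 2, length(c_bounds) == 2,
            all(r1_bounds > 0), all(c_bounds > 0),
            r1_bounds[1] < r1_bounds[2], c_bounds[1] < c_bounds[2],
            grid_n >= 2)
  structure(list(fixed = fixed[c("cpe_t", "cpe_p", "r2")],
                 r1_bounds = r1_bounds, c_bounds = c_bounds,
                 grid_n = as.integer(grid_n), grid_spacing = grid_spacing),
            class = "vw_fit_config")
}

vw_window <- function(waveform, pulse) {
  onset <- require_onset(waveform)
  span <- 2 * pulse$t0 + pulse$gap
  # fit from onset through the pulse plus an equal-length post-pulse tail
  to <- min(onset + 2 * span, waveform$times[length(waveform$times)])
  which(waveform$times >= onset & waveform$times <= to)
}

#' Sum of squared voltage residuals for candidate bulk elements
#'
#' Simulates the circuit's response (fixed CPE and R2 from `config`,
#' candidate `r1` and `c`) over the fitting window — pulse onset through the
#' pulse plus an equal-length decay tail — and returns the sum of squared
#' differences to the measured waveform.
#'
#' @param waveform An aligned [voltage_waveform()].
#' @param r1 Candidate bulk resistance, ohm.
#' @param c Candidate bulk capacitance, farad.
#' @param config A [vw_fit_config()].
#' @param pulse The stimulating [pulse_spec()].
#' @return Scalar sum of squared residuals, V^2.
#' @export
vw_residual <- function(waveform, r1, c, config, pulse) {
  stopifnot(inherits(config, "vw_fit_config"))
  idx <- vw_window(waveform, pulse)
  params <- circuit_params(config$fixed$cpe_t, config$fixed$cpe_p,
                           r1, c, config$fixed$r2)
  sim <- simulate_waveform(params, pulse,
                           waveform$times[idx] - waveform$onset_time)
  sum((waveform$mean_v[idx] - sim$mean_v)^2)
}

# Precomputed fast objective for the R1/C search: the CPE and R2 step
# contributions do not depend on (r1, c) and are evaluated once.
vw_objective_factory <- function(waveform, config, pulse) {
  idx <- vw_window(waveform, pulse)
  t_rel <- waveform$times[idx] - waveform$onset_time
  v_meas <- waveform$mean_v[idx]
  st <- pulse_steps(pulse)
  sgn <- if (pulse$polarity == "anodic") -1 else 1
  fx <- config$fixed
  tau <- lapply(st$times, function(t0) t_rel - t0)
  on <- lapply(tau, function(x) x >= 0)
  v_fixed <- numeric(length(t_rel))
  for (k in seq_along(tau)) {
    tt <- tau[[k]][on[[k]]]
    v_fixed[on[[k]]] <- v_fixed[on[[k]]] + st$amps[k] *
      (tt^fx$cpe_p / (fx$cpe_t * gamma(fx$cpe_p + 1)) + fx$r2)
  }
  list(
    # value and gradient of ssq w.r.t. (r1, c)
    eval = function(r1, c) {
      v <- v_fixed
      d_r1 <- numeric(length(t_rel))
      d_c <- numeric(length(t_rel))
      for (k in seq_along(tau)) {
        m <- on[[k]]
        a <- tau[[k]][m] / (r1 * c)
        e <- exp(-a)
        v[m] <- v[m] + st$amps[k] * r1 * (1 - e)
        d_r1[m] <- d_r1[m] + st$amps[k] * (1 - e - a * e)
        d_c[m] <- d_c[m] + st$amps[k] * (-r1 * a * e / c)
      }
      res <- sgn * v - v_meas
      list(ssq = sum(res^2),
           grad = c(2 * sum(res * sgn * d_r1), 2 * sum(res * sgn * d_c)))
    },
    n = length(t_rel)
  )
}

#' Fit R1 and C from a voltage waveform by bounded grid multistart
#'
#' Runs a bounded local least-squares search (L-BFGS-B on coordinates
#' normalised to the bounds, analytic gradient) from every unique pair of
#' `grid_n` spaced start values per element and returns the solution with
#' the lowest sum of squares. Solutions within 0.1% of a bound are flagged
#' as capped. The procedure is fully deterministic.
#'
#' @inheritParams vw_residual
#' @return A list of class `vw_fit_result`: `r1`, `c`, `ssq`, `capped_r1`,
#'   `capped_c`, `start_used` (the winning start pair), `n_failed` (starts
#'   discarded for non-finite objectives).
#' @export
vw_fit <- function(waveform, config, pulse) {
  stopifnot(inherits(config, "vw_fit_config"))
  obj <- vw_objective_factory(waveform, config, pulse)
  lo <- c(config$r1_bounds[1], config$c_bounds[1])
  hi <- c(config$r1_bounds[2], config$c_bounds[2])
  grid1 <- function(b) {
    if (config$grid_spacing == "linear") {
      seq(b[1], b[2], length.out = config$grid_n)
    } else {
      exp(seq(log(b[1]), log(b[2]), length.out = config$grid_n))
    }
  }
  starts <- expand.grid(r1 = grid1(config$r1_bounds),
                        c = grid1(config$c_bounds))
  # search in coordinates normalised to [0, 1] per element
  to_u <- function(x) (x - lo) / (hi - lo)
  from_u <- function(u) lo + u * (hi - lo)
  fn <- function(u) obj$eval(from_u(u)[1], from_u(u)[2])$ssq
  gr <- function(u) obj$eval(from_u(u)[1], from_u(u)[2])$grad * (hi - lo)

  best <- NULL
  n_failed <- 0L
  for (i in seq_len(nrow(starts))) {
    u0 <- to_u(c(starts$r1[i], starts$c[i]))
    res <- tryCatch(
      stats::optim(u0, fn, gr, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1, 1),
                   control = list(factr = 1e4, maxit = 200)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) {
      n_failed <- n_failed + 1L
      next
    }
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$start <- c(r1 = starts$r1[i], c = starts$c[i])
    }
  }
  if (is.null(best)) stop("all ", nrow(starts), " starts failed")
  sol <- from_u(best$par)
  cap_tol <- 1e-3
  structure(list(
    r1 = sol[1], c = sol[2], ssq = best$value,
    capped_r1 = sol[1] <= lo[1] * (1 + cap_tol) || sol[1] >= hi[1] * (1 - cap_tol),
    capped_c = sol[2] <= lo[2] * (1 + cap_tol) || sol[2] >= hi[2] * (1 - cap_tol),
    start_used = best$start, n_failed = n_failed
  ), class = "vw_fit_result")
}

#' @export
print.vw_fit_result <- function(x, ...) {
  cat("<vw_fit_result> R1 =", format(x$r1, digits = 5),
      if (x$capped_r1) "Ohm (CAPPED)" else "Ohm",
      " C =", format(x$c, digits = 4),
      if (x$capped_c) "F (CAPPED)" else "F",
      " ssq =", format(x$ssq, digits = 4), "V^2\n")
  invisible(x)
}
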