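#' Quality-control screen for an EIS recording
#'
#' Applies the three exclusion rules used to weed out broken electrodes,
#' air bubbles and unstable sweeps before fitting. All rules operate on the
#' mean and per-frequency standard deviation across repeats:
#'
#' * **R1** — the upper quartile (75th percentile over frequencies) of the
#'   per-frequency phase-angle standard deviation exceeds 4 degrees;
#' * **R2** — the mean impedance magnitude at 10 Hz exceeds 50 kOhm;
#' * **R3** — the mean phase angle lies strictly between -20 and 0 degrees
#'   at any frequency from 10 Hz to 1 kHz (near-resistive behaviour where
#'   the interface should be capacitive).
#'
#' @param recording An [eis_recording()] with at least two repeats.
#' @return A list of class `qc_result` with elements `keep` (logical) and
#'   `reasons` (data frame with columns `rule` and `value`; zero rows when
#'   the recording is kept).
#' @export
qc_screen <- function(recording) {
  stopifnot(inherits(recording, "eis_recording"))
  if (length(recording$repeats) < 2) {
    stop("qc_screen needs at least two repeats (standard deviation undefined)")
  }
  m <- mean_spectrum(recording)
  reasons <- data.frame(rule = character(), value = numeric())

  q75 <- as.numeric(stats::quantile(m$phase_std, 0.75))
  if (q75 > 4) {
    reasons <- rbind(reasons, data.frame(rule = "R1", value = q75))
  }
  z10 <- m$z_mag[which.min(abs(log10(m$frequencies) - 1))]
  if (z10 > 50e3) {
    reasons <- rbind(reasons, data.frame(rule = "R2", value = z10))
  }
  band <- m$frequencies >= 10 & m$frequencies <= 1e3
  bad <- band & m$phase_deg > -20 & m$phase_deg < 0
  if (any(bad)) {
    reasons <- rbind(reasons,
                     data.frame(rule = "R3",
                                value = m$phase_deg[which(bad)[1]]))
  }
  structure(list(keep = nrow(reasons) == 0, reasons = reasons),
            class = "qc_result")
}

# complex model curve for either circuit
model_z <- function(params, frequencies) {
  if (inherits(params, "circuit_params")) {
    circuit_impedance(params, frequencies)
  } else if (inherits(params, "simple_circuit_params")) {
    simple_circuit_impedance(params, frequencies)
  } else stop("params must be circuit_params or simple_circuit_params")
}

#' Modulus-weighted mean squared residual of a circuit fit
#'
#' The complex calc-modulus weighting used for EIS fitting: each frequency
#' contributes its squared complex residual normalised by the squared
#' modulus,
#' `100 / N * sum(((Re Z - Re Zhat)^2 + (Im Z - Im Zhat)^2) / |Z|^2)`.
#' The result is on a percentage scale and is proportional to the average
#' squared fractional error between data and model.
#'
#' @param spectrum An [impedance_spectrum()] (the data).
#' @param params [circuit_params()] or [simple_circuit_params()].
#' @param weighting `"data"` (default) normalises by the measured modulus,
#'   `"model"` by the fitted modulus.
#' @return Scalar weighted mean squared residual, percent.
#' @export
weighted_ssq <- function(spectrum, params, weighting = c("data", "model")) {
  weighting <- match.arg(weighting)
  z <- spectrum_z(spectrum)
  zhat <- model_z(params, spectrum$frequencies)
  wmod <- if (weighting == "data") Mod(z) else Mod(zhat)
  if (any(wmod == 0)) stop("zero-magnitude point: weighting undefined")
  100 * mean(Mod(z - zhat)^2 / wmod^2)
}

fit_bounds <- function(name) {
  # EIS fits are effectively unconstrained; cpe_p additionally capped at 1
  if (name == "cpe_p") c(1e-12, 1) else c(1e-12, 1e6)
}

#' Fit a circuit model to an impedance spectrum
#'
#' Bounded complex nonlinear least squares with calc-modulus weighting:
#' the Levenberg-Marquardt minimiser runs on log-transformed free elements
#' (elements span several orders of magnitude and must stay positive), with
#' an iteration cap of 100 and a cost tolerance of 1e-10. Elements named in
#' `fixed_elements` are held at their start value and returned unchanged.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param start Start parameters ([circuit_params()] or
#'   [simple_circuit_params()]); see [start_values()].
#' @param fixed_elements Character vector of element names to hold fixed
#'   (e.g. `"r2"`); empty by default.
#' @param weighting Passed to [weighted_ssq()].
#' @param max_iter Iteration cap (default 100).
#' @return A list of class `fit_result`: `params`, `fixed_elements`,
#'   `weighted_ssq` (percent), `n_iterations`, `converged`.
#' @export
fit_spectrum <- function(spectrum, start, fixed_elements = character(),
                         weighting = c("data", "model"), max_iter = 100L) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  nm <- if (inherits(start, "circuit_params")) element_names("full")
        else element_names("simple")
  if (!all(fixed_elements %in% nm)) {
    stop("unknown element in fixed_elements: ",
         paste(setdiff(fixed_elements, nm), collapse = ", "))
  }
  free <- setdiff(nm, fixed_elements)
  if (length(free) == 0) stop("all elements fixed; nothing to fit")

  z <- spectrum_z(spectrum)
  n <- length(z)
  cls <- class(start)
  make_params <- function(par_log) {
    p <- unclass(start)
    p[free] <- exp(par_log)
    structure(p, class = cls)
  }
  resid_fn <- function(par_log) {
    p <- make_params(par_log)
    zhat <- model_z(p, spectrum$frequencies)
    wmod <- if (weighting == "data") Mod(z) else Mod(zhat)
    r <- c(Re(z - zhat), Im(z - zhat)) / c(wmod, wmod)
    if (any(!is.finite(r))) {
      stop("non-finite residuals at parameters: ",
           paste(sprintf("%s=%.4g", free, exp(par_log)), collapse = ", "))
    }
    r
  }
  lower <- log(vapply(free, function(e) fit_bounds(e)[1], numeric(1)))
  upper <- log(vapply(free, function(e) fit_bounds(e)[2], numeric(1)))
  p0 <- pmin(pmax(log(unlist(unclass(start)[free])), lower), upper)

  # The low-frequency capacitor-formula start can overshoot the bulk
  # capacitance by orders of magnitude (the CPE, not C, carries the 10 Hz
  # magnitude), which strands a single local search. Launch the bounded LM
  # from a deterministic ladder of capacitance start decades and keep the
  # lowest-cost solution.
  cap_name <- intersect(c("c", "c_pol"), free)
  ladders <- if (length(cap_name) == 1) {
    lapply(c(1, 0, -1, -2, -3, -4, -5), function(k) {
      p <- p0
      p[cap_name] <- pmin(pmax(p[cap_name] + k * log(10),
                               lower[cap_name]), upper[cap_name])
      p
    })
  } else list(p0)

  fit <- NULL
  for (pstart in ladders) {
    f <- minpack.lm::nls.lm(
      par = pstart, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-10, ptol = 1e-10))
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
  }
  params <- make_params(fit$par)
  structure(list(
    params = params,
    fixed_elements = fixed_elements,
    weighted_ssq = 100 * fit$deviance / n,
    n_iterations = fit$niter,
    converged = fit$info %in% 1:4
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> weighted ssq =", format(x$weighted_ssq, digits = 4),
      "%  iterations =", x$n_iterations,
      " converged =", x$converged, "\n")
  if (length(x$fixed_elements)) {
    cat("  fixed:", paste(x$fixed_elements, collapse = ", "), "\n")
  }
  print(x$params)
  invisible(x)
}

#' Fit the full circuit across a time course of recordings
#'
#' Reproduces the longitudinal fitting convention: the first timepoint that
#' passes [qc_screen()] is fitted with all five elements free from
#' [start_values()]; R2 (medium + ground path, not expected to change) is
#' then fixed at that first fitted value for all later timepoints; and each
#' subsequent fit is warm-started from the previous timepoint's result.
#' QC-excluded timepoints yield explicit gaps (`fit = NULL`), never
#' interpolations.
#'
#' @param recordings List of [eis_recording()] for one electrode, sorted by
#'   ascending day.
#' @param cpe_p_init Start value for the CPE exponent at the first kept
#'   timepoint.
#' @param weighting Passed to [fit_spectrum()].
#' @return A list of class `eis_timecourse`; one entry per recording with
#'   elements `electrode_id`, `day`, `construct_on`, `qc` and `fit`
#'   (NULL when excluded).
#' @export
fit_timecourse <- function(recordings, cpe_p_init = 0.8,
                           weighting = c("data", "model")) {
  weighting <- match.arg(weighting)
  stopifnot(is.list(recordings), length(recordings) >= 1)
  days <- vapply(recordings, function(r) r$day, integer(1))
  if (is.unsorted(days, strictly = TRUE)) {
    stop("recordings must be sorted by strictly increasing day")
  }
  out <- vector("list", length(recordings))
  prev_fit <- NULL
  r2_fixed <- NULL
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    qc <- qc_screen(rec)
    fit <- NULL
    if (qc$keep) {
      m <- mean_spectrum(rec)
      if (is.null(prev_fit)) {
        fit <- fit_spectrum(m, start_values(m, cpe_p_init),
                            fixed_elements = character(),
                            weighting = weighting)
        r2_fixed <- fit$params$r2
      } else {
        start <- prev_fit$params
        start$r2 <- r2_fixed
        fit <- fit_spectrum(m, start, fixed_elements = "r2",
                            weighting = weighting)
      }
      prev_fit <- fit
    }
    out[[i]] <- list(electrode_id = rec$electrode_id, day = rec$day,
                     construct_on = rec$construct_on, qc = qc, fit = fit)
  }
  if (is.null(prev_fit)) stop("no timepoint passed the QC screen")
  structure(out, class = "eis_timecourse")
}
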