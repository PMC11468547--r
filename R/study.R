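#' Configuration of an end-to-end fibrosis study analysis
#'
#' Exactly one input mode must be set: file paths (`eis_csv`, optionally
#' `waveform_csv`) or a synthetic [cohort_config()].
#'
#' @param eis_csv,waveform_csv Input CSV paths (see [read_eis_csv()],
#'   [read_waveform_csv()]), or NULL in synthetic mode.
#' @param cohort A [cohort_config()], or NULL in file mode.
#' @param pulse The stimulating [pulse_spec()] (default: 50 uA, 50 us,
#'   no gap, cathodic-leading).
#' @param baseline_day Normalisation / fixing day (default 2).
#' @param vw_grid_n Starts per dimension for the reverse waveform fit.
#' @param vw_r1_bounds,vw_c_bounds Bounds for the reverse fit.
#' @param eis_only Skip all waveform stages (QC + EIS fitting only).
#' @param seed Seed for any randomness (synthetic mode).
#' @return An object of class `study_config`.
#' @export
study_config <- function(eis_csv = NULL, waveform_csv = NULL, cohort = NULL,
                         pulse = pulse_spec(50e-6, 50e-6),
                         baseline_day = 2L, vw_grid_n = 30L,
                         vw_r1_bounds = c(50, 5000),
                         vw_c_bounds = c(1e-13, 1e-7),
                         eis_only = FALSE, seed = 1L) {
  synthetic <- !is.null(cohort)
  if (synthetic == !is.null(eis_csv)) {
    stop("set exactly one of (eis_csv, cohort)")
  }
  if (synthetic && !inherits(cohort, "cohort_config")) {
    stop("cohort must be a cohort_config")
  }
  structure(list(eis_csv = eis_csv, waveform_csv = waveform_csv,
                 cohort = cohort, pulse = pulse,
                 baseline_day = as.integer(baseline_day),
                 vw_grid_n = as.integer(vw_grid_n),
                 vw_r1_bounds = vw_r1_bounds, vw_c_bounds = vw_c_bounds,
                 eis_only = isTRUE(eis_only), seed = seed),
            class = "study_config")
}

fit_params_row <- function(entry) {
  f <- entry$fit
  data.frame(electrode_id = entry$electrode_id, day = entry$day,
             construct_on = entry$construct_on,
             kept = !is.null(f),
             cpe_t = if (is.null(f)) NA else f$params$cpe_t,
             cpe_p = if (is.null(f)) NA else f$params$cpe_p,
             r1 = if (is.null(f)) NA else f$params$r1,
             c = if (is.null(f)) NA else f$params$c,
             r2 = if (is.null(f)) NA else f$params$r2,
             weighted_ssq = if (is.null(f)) NA else f$weighted_ssq,
             converged = if (is.null(f)) NA else f$converged)
}

safe_cor <- function(x, y, label) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(data.frame(comparison = label, r = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  pc <- pearson_ci(x[ok], y[ok])
  data.frame(comparison = label, r = pc$r, ci_low = pc$ci_low,
             ci_high = pc$ci_high, p_value = pc$p_value, n = pc$n)
}

#' Run the full fibrosis-study analysis chain
#'
#' Chains QC screening, longitudinal EIS circuit fitting, waveform
#' preprocessing, marker extraction (contact impedance, SPPR, SPPR slope),
#' reverse waveform fitting of R1 and C, and the marker/element
#' correlation table:
#' SPPR slope against the EIS-fitted R1 and C at each slope's final
#' included day; reverse-fitted against EIS-fitted R1 and C at matched
#' electrode/timepoints, reported for all fits, with capped fits excluded,
#' and (for R1) additionally excluding reverse fits above 2 kOhm.
#'
#' @param config A [study_config()].
#' @return An object of class `study_report` with tidy tables
#'   `eis_fits`, `qc_ledger`, `markers`, `sppr_slopes`, `vw_fits`,
#'   `correlations`, and a `manifest` list. Statistical testing beyond the
#'   correlation table (ANOVA etc.) is left to downstream tools.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  synthetic <- !is.null(config$cohort)

  cohort <- NULL
  if (synthetic) {
    cohort <- make_cohort(config$cohort)
    by_electrode <- lapply(cohort$electrodes, function(el) el$eis)
  } else {
    recs <- read_eis_csv(config$eis_csv)
    ids <- vapply(recs, function(r) as.character(r$electrode_id), character(1))
    by_electrode <- lapply(unique(ids), function(id) recs[ids == id])
    waveform_sets <- if (!config$eis_only) {
      if (is.null(config$waveform_csv)) stop("waveform_csv required unless eis_only")
      read_waveform_csv(config$waveform_csv)
    }
    if (!config$eis_only && length(waveform_sets) == 0) {
      stop("waveform file contains no usable records (use eis_only = TRUE ",
           "for an EIS-only analysis)")
    }
  }

  eis_fits <- list()
  qc_rows <- list()
  marker_rows <- list()
  slope_rows <- list()
  vw_rows <- list()
  timecourses <- list()

  for (e in seq_along(by_electrode)) {
    recs <- by_electrode[[e]]
    id <- as.character(recs[[1]]$electrode_id)
    tc <- tryCatch(fit_timecourse(recs), error = function(err) NULL)
    if (is.null(tc)) {
      for (rec in recs) {
        qc <- qc_screen(rec)
        qc_rows[[length(qc_rows) + 1]] <- data.frame(
          electrode_id = id, day = rec$day, kept = qc$keep,
          reasons = paste(qc$reasons$rule, collapse = ";"))
      }
      next
    }
    timecourses[[id]] <- tc
    for (entry in tc) {
      eis_fits[[length(eis_fits) + 1]] <- fit_params_row(entry)
      qc_rows[[length(qc_rows) + 1]] <- data.frame(
        electrode_id = id, day = entry$day, kept = entry$qc$keep,
        reasons = paste(entry$qc$reasons$rule, collapse = ";"))
    }

    if (config$eis_only) next

    # baseline-day fit is required to fix the interface elements for VW fitting
    base_fit <- NULL
    for (entry in tc) {
      if (entry$day == config$baseline_day && !is.null(entry$fit)) {
        base_fit <- entry$fit
      }
    }
    vw_cfg <- if (!is.null(base_fit)) {
      vw_fit_config(fixed = list(cpe_t = base_fit$params$cpe_t,
                                 cpe_p = base_fit$params$cpe_p,
                                 r2 = base_fit$params$r2),
                    r1_bounds = config$vw_r1_bounds,
                    c_bounds = config$vw_c_bounds,
                    grid_n = config$vw_grid_n)
    }

    days_ci <- integer(); ci_vals <- numeric(); sppr_vals <- numeric()
    con_flags <- logical()
    for (j in seq_along(tc)) {
      entry <- tc[[j]]
      if (is.null(entry$fit)) next  # waveforms only analysed when EIS kept
      raw <- if (synthetic) {
        cohort_waveforms(cohort, e, j, config$pulse)
      } else {
        ws <- waveform_sets[[id]][[as.character(entry$day)]]
        if (is.null(ws)) next
        ws
      }
      wf <- preprocess(raw)
      days_ci <- c(days_ci, entry$day)
      ci_vals <- c(ci_vals, contact_impedance(wf, config$pulse))
      sppr_vals <- c(sppr_vals, sppr(wf, config$pulse))
      con_flags <- c(con_flags, entry$construct_on)

      if (!is.null(vw_cfg)) {
        vf <- vw_fit(wf, vw_cfg, config$pulse)
        vw_rows[[length(vw_rows) + 1]] <- data.frame(
          electrode_id = id, day = entry$day, construct_on = entry$construct_on,
          vw_r1 = vf$r1, vw_c = vf$c, ssq = vf$ssq,
          capped_r1 = vf$capped_r1, capped_c = vf$capped_c,
          eis_r1 = entry$fit$params$r1, eis_c = entry$fit$params$c)
      }
    }
    if (length(days_ci)) {
      ms <- marker_series(id, days_ci, ci_vals, sppr_vals, con_flags)
      if (config$baseline_day %in% ms$day) {
        ms <- normalize_series(ms, config$baseline_day)
      } else {
        ms$rel_contact_impedance <- NA_real_
        ms$rel_sppr <- NA_real_
      }
      marker_rows[[length(marker_rows) + 1]] <- as.data.frame(ms)
      sl <- sppr_slope(ms)
      slope_rows[[length(slope_rows) + 1]] <- data.frame(
        electrode_id = id, refused = sl$refused,
        slope = if (sl$refused) NA_real_ else sl$slope,
        final_day = if (sl$refused) NA_integer_ else sl$final_day,
        n = if (sl$refused) NA_integer_ else sl$n)
    }
  }

  if (length(eis_fits) == 0) stop("no electrode produced a usable EIS fit")
  eis_fits <- do.call(rbind, eis_fits)
  qc_ledger <- do.call(rbind, qc_rows)
  markers <- if (length(marker_rows)) do.call(rbind, marker_rows) else NULL
  slopes <- if (length(slope_rows)) do.call(rbind, slope_rows) else NULL
  vw_fits <- if (length(vw_rows)) do.call(rbind, vw_rows) else NULL

  correlations <- list()
  if (!is.null(slopes)) {
    sl <- slopes[!slopes$refused, ]
    final_r1 <- final_c <- rep(NA_real_, nrow(sl))
    for (i in seq_len(nrow(sl))) {
      row <- eis_fits[eis_fits$electrode_id == sl$electrode_id[i] &
                        eis_fits$day == sl$final_day[i] & eis_fits$kept, ]
      if (nrow(row) == 1) { final_r1[i] <- row$r1; final_c[i] <- row$c }
    }
    correlations[[length(correlations) + 1]] <-
      safe_cor(sl$slope, final_r1, "sppr_slope_vs_final_r1")
    correlations[[length(correlations) + 1]] <-
      safe_cor(sl$slope, final_c, "sppr_slope_vs_final_c")
  }
  if (!is.null(vw_fits)) {
    correlations[[length(correlations) + 1]] <-
      safe_cor(vw_fits$vw_r1, vw_fits$eis_r1, "vw_vs_eis_r1_all")
    unc <- vw_fits[!vw_fits$capped_r1 & !vw_fits$capped_c, ]
    correlations[[length(correlations) + 1]] <-
      safe_cor(unc$vw_r1, unc$eis_r1, "vw_vs_eis_r1_uncapped")
    unc2 <- unc[unc$vw_r1 <= 2000, ]
    correlations[[length(correlations) + 1]] <-
      safe_cor(unc2$vw_r1, unc2$eis_r1, "vw_vs_eis_r1_uncapped_le2k")
    correlations[[length(correlations) + 1]] <-
      safe_cor(unc$vw_c, unc$eis_c, "vw_vs_eis_c_uncapped")
  }
  correlations <- if (length(correlations)) do.call(rbind, correlations) else NULL

  structure(list(
    eis_fits = eis_fits, qc_ledger = qc_ledger, markers = markers,
    sppr_slopes = slopes, vw_fits = vw_fits, correlations = correlations,
    truth = if (synthetic) cohort$truth else NULL,
    manifest = list(
      mode = if (synthetic) "synthetic" else "files",
      seed = config$seed,
      baseline_day = config$baseline_day,
      pulse = unclass(config$pulse),
      vw_grid_n = config$vw_grid_n,
      n_electrodes = length(by_electrode))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", x$manifest$n_electrodes, " electrodes (",
      x$manifest$mode, " mode)\n", sep = "")
  cat("  EIS fits:", sum(x$eis_fits$kept), "kept /", nrow(x$eis_fits), "\n")
  if (!is.null(x$vw_fits)) {
    cat("  VW fits:", nrow(x$vw_fits), "(",
        sum(x$vw_fits$capped_r1 | x$vw_fits$capped_c), "capped )\n")
  }
  if (!is.null(x$correlations)) {
    cat("  correlations:\n")
    print(x$correlations, digits = 3)
  }
  invisible(x)
}
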