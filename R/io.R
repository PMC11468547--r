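check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

check_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("file ", path, ", column ", col, ": non-numeric value at row(s) ",
             paste(utils::head(bad + 1L, 5), collapse = ", "))
      }
      df[[col]] <- vn
    }
  }
  df
}

#' Read EIS recordings from a long-format CSV
#'
#' Expected columns: `electrode_id`, `day`, `repeat`, `frequency_hz`,
#' `z_mag_ohm`, `phase_deg`, and optionally `construct_on`. Rows are
#' grouped into one [eis_recording()] per (electrode, day).
#'
#' @param path CSV file path.
#' @return List of [eis_recording()], ordered by electrode then day.
#' @export
read_eis_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("electrode_id", "day", "repeat", "frequency_hz",
                      "z_mag_ohm", "phase_deg"), path)
  df <- check_numeric(df, c("day", "repeat", "frequency_hz", "z_mag_ohm",
                            "phase_deg"), path)
  key <- paste(df$electrode_id, df$day, df$`repeat`, df$frequency_hz)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (electrode, day, repeat, frequency) keys in ", path,
         " at rows ", paste(utils::head(d + 1L, 6), collapse = ", "))
  }
  if (is.null(df$construct_on)) df$construct_on <- TRUE
  out <- list()
  for (el in unique(df$electrode_id)) {
    de <- df[df$electrode_id == el, ]
    for (day in sort(unique(de$day))) {
      dd <- de[de$day == day, ]
      reps <- lapply(sort(unique(dd$`repeat`)), function(r) {
        dr <- dd[dd$`repeat` == r, ]
        o <- order(dr$frequency_hz)
        impedance_spectrum(dr$frequency_hz[o], dr$z_mag_ohm[o],
                           dr$phase_deg[o])
      })
      out[[length(out) + 1]] <-
        eis_recording(el, day, reps, construct_on = all(dd$construct_on))
    }
  }
  out
}

#' Write EIS recordings to a long-format CSV
#'
#' @param recordings List of [eis_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eis_csv <- function(recordings, path) {
  rows <- lapply(recordings, function(rec) {
    do.call(rbind, lapply(seq_along(rec$repeats), function(r) {
      s <- rec$repeats[[r]]
      data.frame(electrode_id = rec$electrode_id, day = rec$day,
                 `repeat` = r, frequency_hz = s$frequencies,
                 z_mag_ohm = s$z_mag, phase_deg = s$phase_deg,
                 construct_on = rec$construct_on, check.names = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read raw waveform repeats from a long-format CSV
#'
#' Expected columns: `electrode_id`, `day`, `pulse_polarity`, `repeat`,
#' `time_s`, `voltage_v`. Time zero marks pulse onset; negative times are
#' the pre-stimulus segment.
#'
#' @param path CSV file path.
#' @return Nested list: `[[electrode_id]][[as.character(day)]]` holding a
#'   [raw_waveform_set()] (cathodic polarity preferred when both present).
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("electrode_id", "day", "pulse_polarity", "repeat",
                      "time_s", "voltage_v"), path)
  df <- check_numeric(df, c("day", "repeat", "time_s", "voltage_v"), path)
  out <- list()
  for (el in unique(df$electrode_id)) {
    de <- df[df$electrode_id == el, ]
    out[[el]] <- list()
    for (day in sort(unique(de$day))) {
      dd <- de[de$day == day, ]
      pol <- if ("cathodic" %in% dd$pulse_polarity) "cathodic" else dd$pulse_polarity[1]
      dp <- dd[dd$pulse_polarity == pol, ]
      reps_id <- sort(unique(dp$`repeat`))
      mats <- sapply(reps_id, function(r) {
        dr <- dp[dp$`repeat` == r, ]
        dr$voltage_v[order(dr$time_s)]
      })
      t0 <- sort(dp$time_s[dp$`repeat` == reps_id[1]])
      fs <- 1 / check_uniform(t0)
      out[[el]][[as.character(day)]] <-
        raw_waveform_set(fs, mats, pre_stimulus_samples = sum(t0 < 0))
    }
  }
  out
}

#' Write raw waveform repeats to a long-format CSV
#'
#' @param sets Nested list as returned by [read_waveform_csv()]:
#'   `[[electrode_id]][[day]]` holding [raw_waveform_set()] objects.
#' @param path Output CSV path.
#' @param pulse_polarity Polarity label written for every trace.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(sets, path, pulse_polarity = "cathodic") {
  rows <- list()
  for (el in names(sets)) {
    for (day in names(sets[[el]])) {
      ws <- sets[[el]][[day]]
      times <- (seq_len(nrow(ws$repeats)) - 1 - ws$pre_stimulus_samples) /
        ws$sampling_rate
      for (r in seq_len(ncol(ws$repeats))) {
        rows[[length(rows) + 1]] <- data.frame(
          electrode_id = el, day = as.numeric(day),
          pulse_polarity = pulse_polarity, `repeat` = r,
          time_s = times, voltage_v = ws$repeats[, r], check.names = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write patient telemetry records to CSV
#'
#' @param telemetry List of [patient_telemetry()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(telemetry, path) {
  rows <- lapply(telemetry, function(tl) {
    rbind(
      data.frame(patient_id = tl$patient_id, electrode = tl$electrode,
                 visit = tl$visit, offset_us = tl$phase1$offset_us,
                 phase = 1, voltage_v = tl$phase1$voltage_v,
                 current_a = tl$input_current, mcl_cl = tl$mcl_cl),
      data.frame(patient_id = tl$patient_id, electrode = tl$electrode,
                 visit = tl$visit, offset_us = tl$phase2$offset_us,
                 phase = 2, voltage_v = tl$phase2$voltage_v,
                 current_a = tl$input_current, mcl_cl = tl$mcl_cl))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read patient telemetry from CSV
#'
#' Expected columns: `patient_id`, `electrode`, `visit`, `offset_us`,
#' `phase` (1 or 2), `voltage_v`, `current_a`, and optionally `mcl_cl`.
#'
#' @param path CSV file path.
#' @return List of [patient_telemetry()], one per (patient, electrode,
#'   visit).
#' @export
read_patient_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("patient_id", "electrode", "visit", "offset_us",
                      "phase", "voltage_v", "current_a"), path)
  df <- check_numeric(df, c("electrode", "offset_us", "phase", "voltage_v",
                            "current_a"), path)
  if (is.null(df$mcl_cl)) df$mcl_cl <- NA_real_
  keys <- unique(df[, c("patient_id", "electrode", "visit")])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    d <- df[df$patient_id == k$patient_id & df$electrode == k$electrode &
              df$visit == k$visit, ]
    patient_telemetry(
      k$patient_id, k$electrode, k$visit,
      phase1 = d[d$phase == 1, c("offset_us", "voltage_v")],
      phase2 = d[d$phase == 2, c("offset_us", "voltage_v")],
      input_current = d$current_a[1],
      mcl_cl = d$mcl_cl[1])
  })
}

#' Write a study report to a directory
#'
#' Emits the tidy tables of a [run_study()] report: `eis_fits.csv`,
#' `qc_ledger.csv`, `markers.csv`, `sppr_slopes.csv`, `vw_fits.csv`,
#' `correlations.csv`, plus a `manifest.json` carrying the seed and
#' configuration summary.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("eis_fits", "qc_ledger", "markers", "sppr_slopes", "vw_fits",
            "correlations")
  for (tb in tabs) {
    if (is.null(report[[tb]])) next
    utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
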