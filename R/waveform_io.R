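#' Construct and validate a pressure-volume waveform
#'
#' A `pv_waveform` holds one synchronized right-ventricular pressure/volume
#' recording: time in seconds, pressure in mmHg, volume in microlitres,
#' sampled at a nominally constant rate (catheter systems in mice typically
#' record at 1000 Hz). Validation is strict: constructing an object with
#' non-monotone time, non-finite samples, or non-positive volumes is an
#' error, never a silent repair.
#'
#' @param time numeric vector, seconds; strictly increasing, spacing
#'   consistent with `sampling_rate` (median spacing within 1%).
#' @param pressure numeric vector, mmHg; same length as `time`.
#' @param volume numeric vector, microlitres; same length, all `> 0`.
#' @param subject_id,group_label character scalars identifying the recording.
#' @param sampling_rate nominal sampling rate in Hz (default 1000).
#' @return An object of class `pv_waveform`: a list with fields `subject_id`,
#'   `group_label`, `time`, `pressure`, `volume`, `sampling_rate`.
#' @examples
#' t <- seq(0, 0.5, by = 1e-3)
#' w <- pv_waveform(t, 20 + 10 * sin(2 * pi * 9 * t), 15 + 5 * cos(2 * pi * 9 * t))
#' w
#' @export
pv_waveform <- function(time, pressure, volume, subject_id = "unknown",
                        group_label = "unknown", sampling_rate = 1000) {
  time <- as.numeric(time)
  pressure <- as.numeric(pressure)
  volume <- as.numeric(volume)
  n <- length(time)
  if (n < 2L || length(pressure) != n || length(volume) != n)
    stopf("time, pressure and volume must have equal length >= 2 (got %d, %d, %d)",
          n, length(pressure), length(volume))
  bad <- which(!is.finite(time) | !is.finite(pressure) | !is.finite(volume))
  if (length(bad))
    stopf("non-finite samples at indices: %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  dt <- diff(time)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stopf("time must be strictly increasing (violation at index %d)", i + 1L)
  }
  if (any(volume <= 0)) {
    i <- which(volume <= 0)[1L]
    stopf("volume must be positive everywhere (violation at index %d)", i)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be a positive number")
  med_dt <- stats::median(dt)
  if (abs(med_dt - 1 / sampling_rate) > 0.01 / sampling_rate)
    stopf("median sample spacing %.6g s inconsistent with sampling_rate %g Hz",
          med_dt, sampling_rate)
  structure(list(subject_id = as.character(subject_id)[1L],
                 group_label = as.character(group_label)[1L],
                 time = time, pressure = pressure, volume = volume,
                 sampling_rate = sampling_rate),
            class = "pv_waveform")
}

#' @export
print.pv_waveform <- function(x, ...) {
  cat(sprintf("pv_waveform '%s' (%s): %d samples @ %g Hz, %.3f s\n",
              x$subject_id, x$group_label, length(x$time), x$sampling_rate,
              x$time[length(x$time)] - x$time[1L]))
  cat(sprintf("  pressure %.1f..%.1f mmHg, volume %.1f..%.1f uL\n",
              min(x$pressure), max(x$pressure), min(x$volume), max(x$volume)))
  invisible(x)
}

#' @export
plot.pv_waveform <- function(x, type = c("loop", "time"), ...) {
  type <- match.arg(type)
  if (type == "loop") {
    plot(x$volume, x$pressure, type = "l", xlab = "Volume (uL)",
         ylab = "Pressure (mmHg)", main = x$subject_id, ...)
  } else {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    plot(x$time, x$pressure, type = "l", xlab = "Time (s)", ylab = "P (mmHg)", ...)
    plot(x$time, x$volume, type = "l", xlab = "Time (s)", ylab = "V (uL)", ...)
  }
  invisible(x)
}

#' Read a pressure-volume waveform from CSV
#'
#' The on-disk dialect is plain comma-separated text with one header line
#' `time,pressure,volume` (units fixed as s / mmHg / uL). Optional leading
#' comment lines of the form `# key: value` carry metadata (`subject_id`,
#' `group_label`, `sampling_rate`); anything else in comments is ignored.
#'
#' @param path path to the waveform CSV.
#' @param subject_id,group_label,sampling_rate override metadata not present
#'   in the file header comments.
#' @return A validated [pv_waveform].
#' @export
read_pv_waveform <- function(path, subject_id = NULL, group_label = NULL,
                             sampling_rate = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", cl))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  body <- lines[!is_comment]
  if (!length(body)) stopf("no data rows in %s", path)
  df <- utils::read.csv(text = body, check.names = FALSE)
  req <- c("time", "pressure", "volume")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stopf("missing required column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  sr <- sampling_rate %||% (if (!is.null(meta$sampling_rate)) as.numeric(meta$sampling_rate) else
    1 / stats::median(diff(df$time)))
  pv_waveform(df$time, df$pressure, df$volume,
              subject_id = subject_id %||% meta$subject_id %||%
                sub("\\.[^.]*$", "", basename(path)),
              group_label = group_label %||% meta$group_label %||% "unknown",
              sampling_rate = sr)
}

#' Write a pressure-volume waveform to CSV
#'
#' Inverse of [read_pv_waveform]; metadata is stored in `# key: value`
#' comment lines before the header. Samples are written with 10 significant
#' digits, so a write/read round trip reproduces them to that precision.
#'
#' @param w a [pv_waveform].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pv_waveform <- function(w, path) {
  stopifnot(inherits(w, "pv_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", w$subject_id),
               sprintf("# group_label: %s", w$group_label),
               sprintf("# sampling_rate: %.10g", w$sampling_rate),
               "time,pressure,volume"), con)
  writeLines(sprintf("%.10g,%.10g,%.10g", w$time, w$pressure, w$volume), con)
  invisible(path)
}

#' Read a per-animal morphometry/biochemistry table
#'
#' One row per animal with columns `subject_id`, `group_label`, `rv_mass`
#' (mg), `lvs_mass` (mg, left ventricle plus septum), `body_weight` (g),
#' `hematocrit` (%), `ohp` (hydroxyproline, ug per mg RV), `pyd`
#' (pyridinoline, nmol per mg RV) and optionally `aortic_pressure` (mmHg).
#' Assay columns may be missing for individual animals (empty cells become
#' `NA`, never 0); extra columns are preserved untouched.
#'
#' @param path CSV path with a named header row.
#' @return A `data.frame` with one validated row per animal.
#' @export
read_animal_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  validate_animal_table(df)
}

#' @rdname read_animal_table
#' @param df a data.frame of per-animal rows to validate in place.
#' @export
validate_animal_table <- function(df) {
  req <- c("subject_id", "group_label")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stopf("animal table missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stopf("duplicated subject_id: %s",
          paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  chk_pos <- function(col) {
    if (col %in% names(df) && any(!is.na(df[[col]]) & df[[col]] <= 0))
      stopf("%s must be positive (offending subject: %s)", col,
            df$subject_id[which(!is.na(df[[col]]) & df[[col]] <= 0)[1L]])
  }
  for (col in c("rv_mass", "lvs_mass", "body_weight")) chk_pos(col)
  if ("hematocrit" %in% names(df)) {
    bad <- !is.na(df$hematocrit) & (df$hematocrit <= 0 | df$hematocrit >= 100)
    if (any(bad))
      stopf("hematocrit must lie in (0, 100) (offending subject: %s)",
            df$subject_id[which(bad)[1L]])
  }
  for (col in c("ohp", "pyd")) {
    if (col %in% names(df) && any(!is.na(df[[col]]) & df[[col]] < 0))
      stopf("%s must be non-negative", col)
  }
  df
}

#' Write an animal table to CSV
#' @param df validated animal table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_animal_table <- function(df, path) {
  utils::write.csv(validate_animal_table(df), path, row.names = FALSE, na = "")
  invisible(path)
}
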