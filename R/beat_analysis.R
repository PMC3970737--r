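#' Smoothed pressure derivative dP/dt
#'
#' Centered quadratic (Savitzky-Golay) smoothing differentiation. The window
#' suppresses catheter noise while preserving the dP/dt extremes at murine
#' heart rates; endpoints are handled by the filter's one-sided
#' least-squares stencils so the output has the same length as the input.
#'
#' @param pressure pressure samples, mmHg.
#' @param sampling_rate sampling rate, Hz.
#' @param window_ms smoothing window, ms (default 5; must cover >= 3 samples
#'   and be shorter than the signal).
#' @return derivative in mmHg/s, same length as `pressure`.
#' @examples
#' t <- seq(0, 0.1, by = 1e-3)
#' max(smooth_derivative(sin(2 * pi * 10 * t), 1000)) # ~ 2*pi*10
#' @export
smooth_derivative <- function(pressure, sampling_rate, window_ms = 5) {
  n_w <- round(window_ms * sampling_rate / 1000)
  if (n_w < 3) stopf("window_ms must span at least 3 samples")
  if (n_w %% 2 == 0) n_w <- n_w + 1
  if (n_w >= length(pressure)) stopf("smoothing window longer than signal")
  d <- signal::sgolayfilt(pressure, p = 2, n = n_w, m = 1, ts = 1 / sampling_rate)
  as.numeric(d)
}

#' Segment a pressure-volume waveform into cardiac cycles
#'
#' Beats are anchored at dP/dt-max peaks (the sharpest, most noise-robust
#' fiducial in right-ventricular traces), found with a minimum spacing
#' `min_rr_ms`. Each beat is then delimited at end-diastole, located as the
#' pressure minimum in a 20 ms window before its dP/dt-max peak; consecutive
#' beats tile the analyzed span without overlap (`[start_idx, end_idx)`).
#' Within each beat, dP/dt-min is located, and end-systole is assigned by
#' [find_end_systole] (maximal pressure over offset volume).
#'
#' @param w a [pv_waveform].
#' @param min_rr_ms minimum RR interval, ms (default 60, i.e. a 1000 bpm
#'   ceiling).
#' @param window_ms derivative smoothing window, ms.
#' @return A data.frame of class `pv_beats` with one row per complete beat:
#'   `start_idx`, `end_idx`, `ed_idx`, `es_idx`, `dpdt_max_idx`,
#'   `dpdt_min_idx`, `rr_ms`, `extrasystolic`, `in_occlusion`.
#' @export
segment_beats <- function(w, min_rr_ms = 60, window_ms = 5) {
  stopifnot(inherits(w, "pv_waveform"))
  sr <- w$sampling_rate
  dpdt <- smooth_derivative(w$pressure, sr, window_ms)
  min_dist <- max(1L, round(min_rr_ms * sr / 1000))
  # threshold relative to a robust upper quantile so occlusion beats (whose
  # dP/dt max shrinks with preload) are still anchored
  hi <- stats::quantile(dpdt, 0.98, names = FALSE)
  peaks <- find_peaks(dpdt, min_dist = min_dist, min_height = 0.25 * hi)
  if (length(peaks) < 2L) stopf("no beats detected (need >= 2 dP/dt-max peaks)")

  ed_win <- max(1L, as.integer(round(0.020 * sr)))
  # a peak too close to the recording start lacks a full ED search window
  # and would shorten the first RR interval
  peaks <- peaks[peaks - ed_win >= 1L]
  if (length(peaks) < 2L) stopf("no beats detected (need >= 2 dP/dt-max peaks)")
  # ED search runs on smoothed pressure: diastolic pressure is nearly flat
  # at the noise floor, so the raw minimum would jitter the beat boundary
  p_s <- sg_smooth(w$pressure, max(9L, round(0.009 * sr)))
  ed <- vapply(peaks, function(pk) {
    lo <- max(1L, pk - ed_win)
    seg <- p_s[lo:pk]
    # earliest sample within a small band of the window minimum: on a flat
    # diastolic floor the exact argmin is noise-driven, the band is not
    as.integer(lo + which(seg <= min(seg) + 0.1 * diff(range(seg)))[1L] - 1L)
  }, integer(1L))
  # half-open tiling: beat k runs from its ED to the next beat's ED
  n_b <- length(ed) - 1L
  beats <- data.frame(start_idx = ed[seq_len(n_b)],
                      end_idx = ed[seq_len(n_b) + 1L],
                      ed_idx = ed[seq_len(n_b)],
                      es_idx = NA_integer_,
                      dpdt_max_idx = peaks[seq_len(n_b)],
                      dpdt_min_idx = NA_integer_,
                      rr_ms = NA_real_,
                      extrasystolic = FALSE,
                      in_occlusion = FALSE)
  beats$rr_ms <- (w$time[beats$end_idx] - w$time[beats$start_idx]) * 1000
  for (k in seq_len(n_b)) {
    span <- beats$dpdt_max_idx[k]:(beats$end_idx[k] - 1L)
    beats$dpdt_min_idx[k] <- span[which.min(dpdt[span])]
    b <- beats[k, ]
    beats$es_idx[k] <- tryCatch(find_end_systole(w, b, v0 = 0),
                                error = function(e) NA_integer_)
  }
  structure(beats, class = c("pv_beats", "data.frame"))
}

#' Locate the end-systolic sample of one beat
#'
#' End-systole is operationalized as the instant of maximal elastance: the
#' sample maximizing `P / (V - v0)`, restricted to the interval between the
#' beat's dP/dt-max and dP/dt-min landmarks. For steady-state beats `v0 = 0`
#' is conventional; during iterative ESPVR fitting the current `v0` estimate
#' is passed in. Pressure and volume are lightly smoothed before the ratio
#' is formed so a single noise spike cannot claim the maximum. Ties break to
#' the earliest sample.
#'
#' @param w a [pv_waveform].
#' @param beat one row of a `pv_beats` frame (needs `dpdt_max_idx`,
#'   `dpdt_min_idx`).
#' @param v0 volume-axis offset, uL; must be below the beat's minimum volume.
#' @param smooth_ms smoothing window for the ratio, ms (0 disables).
#' @return the end-systolic sample index (into `w`).
#' @export
find_end_systole <- function(w, beat, v0 = 0, smooth_ms = 5) {
  i0 <- beat$dpdt_max_idx[1L]
  i1 <- beat$dpdt_min_idx[1L]
  if (is.na(i1) || i1 <= i0) i1 <- beat$end_idx[1L] - 1L
  span <- i0:i1
  p <- w$pressure[span]
  v <- w$volume[span]
  if (smooth_ms > 0 && length(span) >= 7L) {
    n_w <- max(5L, round(smooth_ms * w$sampling_rate / 1000))
    p <- sg_smooth(p, n_w)
    v <- sg_smooth(v, n_w)
  }
  if (v0 >= min(v)) stopf("v0 (%.3g) must be below the beat's minimum volume (%.3g)",
                          v0, min(v))
  span[which.max(p / (v - v0))]
}

#' Flag extrasystolic beats by RR-interval deviation
#'
#' A beat is flagged when its RR interval deviates from the running median
#' RR (7-beat centered window) by more than `rr_tolerance`; the flag is
#' sticky for the following beat, which absorbs the compensatory pause.
#' With fewer than 3 beats nothing is flagged and a warning is issued.
#'
#' @param beats a `pv_beats` frame from [segment_beats].
#' @param rr_tolerance fractional deviation threshold (default 0.15).
#' @return `beats` with the `extrasystolic` column set.
#' @export
flag_extrasystoles <- function(beats, rr_tolerance = 0.15) {
  n <- nrow(beats)
  if (n < 3L) {
    warnf("fewer than 3 beats: extrasystole flagging skipped")
    return(beats)
  }
  rr <- beats$rr_ms
  med <- stats::runmed(rr, k = min(7L, n - (1 - n %% 2)), endrule = "median")
  dev <- abs(rr - med) / med
  flag <- dev > rr_tolerance
  sticky <- c(FALSE, flag[-n])
  beats$extrasystolic <- flag | sticky
  beats
}

#' Select a steady analysis window of consecutive clean beats
#'
#' Returns the earliest run of at least `n` consecutive beats that are
#' neither flagged extrasystolic nor inside a detected occlusion, mirroring
#' the convention of analyzing at least 10 consecutive cycles free of
#' extrasystolic beats. The entire qualifying run is returned, not just its
#' first `n` beats.
#'
#' @param beats a flagged `pv_beats` frame.
#' @param n minimum run length (default 10).
#' @return the contiguous sub-frame of qualifying beats.
#' @export
select_steady_window <- function(beats, n = 10) {
  ok <- !beats$extrasystolic & !beats$in_occlusion
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= n)
  if (!length(good)) {
    longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    stopf("insufficient steady beats: need %d consecutive clean beats, longest run is %d",
          n, longest)
  }
  g <- good[1L]
  beats[starts[g]:ends[g], , drop = FALSE]
}
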