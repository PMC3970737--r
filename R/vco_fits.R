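#' Detect vena-cava-occlusion transients
#'
#' Scans the per-beat RVSP series (lightly smoothed with a 3-beat running
#' mean) for maximal descending limbs: runs of beats over which RVSP falls
#' essentially monotonically (per-beat rises of up to 2% of baseline are
#' tolerated) by at least `drop_fraction` of the pre-run baseline. Detected
#' beats are flagged `in_occlusion` so steady-state selection skips them.
#'
#' @param w a [pv_waveform].
#' @param beats a `pv_beats` frame from [segment_beats].
#' @param drop_fraction minimum total RVSP drop as a fraction of baseline
#'   (default 0.10).
#' @param min_beats minimum beats in a run (default 4).
#' @return list with `beats` (the input frame with `in_occlusion` set) and
#'   `runs`: a list of `vco_run` objects, each holding `beat_rows` (row
#'   indices into `beats`), `baseline_rvsp` and `span` (sample range).
#'   `runs` is empty when no occlusion is found.
#' @export
detect_occlusion <- function(w, beats, drop_fraction = 0.10, min_beats = 4) {
  n <- nrow(beats)
  rvsp <- vapply(seq_len(n), function(k)
    max(w$pressure[beats$start_idx[k]:(beats$end_idx[k] - 1L)]), numeric(1L))
  if (n < min_beats + 1L) return(list(beats = beats, runs = list()))
  s <- as.numeric(stats::filter(rvsp, rep(1 / 3, 3), sides = 2))
  s[1L] <- rvsp[1L]; s[n] <- rvsp[n]
  runs <- list()
  k <- 1L
  while (k < n) {
    baseline0 <- mean(rvsp[max(1L, k - 5L):k])
    tol <- 0.02 * baseline0
    j <- k
    while (j < n && s[j + 1L] <= s[j] + tol) j <- j + 1L
    found <- FALSE
    if (j - k + 1L >= min_beats &&
        (s[k] - min(s[k:j])) >= drop_fraction * baseline0) {
      # run extent is judged on the smoothed series, but the run ends at the
      # raw-RVSP nadir so recovery counting starts at the true minimum beat;
      # look one beat past the smoothed end, whose 3-beat mean is already
      # lifted by the first recovery beat
      j_ext <- min(j + 1L, n)
      jmin <- k - 1L + which.min(rvsp[k:j_ext])
      # a flat pre-occlusion plateau also satisfies the per-beat tolerance;
      # trim it so the run starts where RVSP actually leaves baseline
      still_base <- which(s[k:jmin] >= 0.97 * baseline0)
      st <- if (length(still_base)) k - 1L + max(still_base) else k
      baseline <- mean(rvsp[max(1L, st - 5L):st])
      rows <- st:jmin
      if (length(rows) >= min_beats &&
          (baseline - rvsp[jmin]) >= drop_fraction * baseline) {
        runs[[length(runs) + 1L]] <- structure(
          list(beat_rows = rows, baseline_rvsp = baseline,
               span = c(beats$start_idx[rows[1L]],
                        beats$end_idx[rows[length(rows)]])),
          class = "vco_run")
        beats$in_occlusion[rows] <- TRUE
        found <- TRUE
        k <- jmin + 1L
      }
    }
    if (!found) k <- k + 1L
  }
  list(beats = beats, runs = runs)
}

#' Iterative end-systolic pressure-volume relation (ESPVR) fit
#'
#' Estimates end-systolic elastance `Ees` and the unstressed volume `V0`
#' from the descending limb of a vena-cava occlusion by the standard
#' iterative scheme: (1) with the current `v0`, locate each beat's
#' end-systolic point as the sample maximizing `P/(V - v0)`
#' ([find_end_systole]); (2) fit a least-squares line through the
#' `(V_es, P_es)` points; (3) update `v0` to the line's volume-axis
#' intercept; repeat until `|delta v0| < tol_v0`. The first beat of the run
#' is dropped (onset transient); iteration starts at `v0 = 0`, safely below
#' murine end-systolic volumes.
#'
#' @param w a [pv_waveform].
#' @param run a `vco_run` from [detect_occlusion].
#' @param beats the `pv_beats` frame the run refers to.
#' @param tol_v0 convergence tolerance on `v0`, uL (default 0.01).
#' @param max_iter maximum iterations (default 50).
#' @return list of class `espvr_fit`: `ees` (mmHg/uL), `v0` (uL), `r2`,
#'   `n_beats`, `iterations`, `converged`, and the final `es_points`.
#' @export
fit_espvr <- function(w, run, beats, tol_v0 = 0.01, max_iter = 50) {
  rows <- run$beat_rows
  if (length(rows) > 1L) rows <- rows[-1L] # drop occlusion-onset beat
  if (length(rows) < 4L)
    stopf("ESPVR fit needs >= 4 descending-limb beats (got %d)", length(rows))
  bsub <- beats[rows, , drop = FALSE]
  # ES coordinates are read from smoothed signals: the raw sample at the
  # selected instant carries the full measurement noise, which both dilutes
  # the slope (noise in V) and couples to the argmax selection
  n_w <- max(9L, round(0.009 * w$sampling_rate))
  p_s <- sg_smooth(w$pressure, n_w)
  v_s <- sg_smooth(w$volume, n_w)
  min_v <- min(vapply(seq_len(nrow(bsub)), function(k)
    min(w$volume[bsub$start_idx[k]:(bsub$end_idx[k] - 1L)]), numeric(1L)))
  v0 <- 0
  iterations <- 0L
  converged <- FALSE
  ves <- pes <- numeric(nrow(bsub))
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (k in seq_len(nrow(bsub))) {
      es <- find_end_systole(w, bsub[k, ], v0 = v0, smooth_ms = 9)
      ves[k] <- v_s[es]; pes[k] <- p_s[es]
    }
    fit <- stats::lm.fit(cbind(1, ves), pes)
    slope <- fit$coefficients[2L]; inter <- fit$coefficients[1L]
    if (!is.finite(slope) || slope <= 0)
      stopf("non-physiological ESPVR: slope %.3g <= 0 over %d beats (RVSP range %.1f-%.1f mmHg)",
            slope, length(pes), min(pes), max(pes))
    v0_new <- -inter / slope
    v0_new <- min(v0_new, min_v - 0.5) # keep the elastance ratio defined
    if (abs(v0_new - v0) < tol_v0) {
      v0 <- v0_new
      converged <- TRUE
      break
    }
    v0 <- v0_new
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pes - mean(pes))^2)
  structure(list(ees = as.numeric(slope), v0 = as.numeric(v0),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_beats = length(pes), iterations = iterations,
                 converged = converged,
                 es_points = data.frame(v_es = ves, p_es = pes)),
            class = "espvr_fit")
}

#' @export
print.espvr_fit <- function(x, ...) {
  cat(sprintf("ESPVR fit: Ees = %.3f mmHg/uL, V0 = %.2f uL (r2 = %.3f, %d beats, %s in %d iter)\n",
              x$ees, x$v0, x$r2, x$n_beats,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Preload-recruitable stroke work (PRSW)
#'
#' Least-squares slope of stroke work (uL mmHg) against end-diastolic
#' volume (uL) across the preload sweep; the slope has units mmHg and the
#' volume-axis intercept `vw` (uL) marks the EDV at which stroke work
#' extrapolates to zero.
#'
#' @param indices data.frame of per-beat indices (needs `sw`, `edv`),
#'   >= 4 beats.
#' @return list of class `prsw_fit`: `prsw` (mmHg), `vw` (uL), `r2`.
#' @export
fit_prsw <- function(indices) {
  if (nrow(indices) < 4L) stopf("PRSW fit needs >= 4 beats")
  edv <- indices$edv; sw <- indices$sw
  if (stats::sd(edv) < 1e-9) stopf("PRSW fit: zero EDV variance across beats")
  fit <- stats::lm.fit(cbind(1, edv), sw)
  slope <- fit$coefficients[2L]; inter <- fit$coefficients[1L]
  ss_res <- sum(fit$residuals^2); ss_tot <- sum((sw - mean(sw))^2)
  structure(list(prsw = as.numeric(slope),
                 vw = as.numeric(-inter / slope),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "prsw_fit")
}

#' Linear end-diastolic pressure-volume relation (EDPVR)
#'
#' Least-squares line through the `(EDV, EDP)` points of the preload sweep;
#' the slope (mmHg/uL) approximates the reciprocal diastolic compliance.
#'
#' @param indices data.frame of per-beat indices (needs `edv`, `rvedp`),
#'   >= 4 beats.
#' @return list of class `edpvr_fit`: `slope` (mmHg/uL), `intercept`
#'   (mmHg), `r2`.
#' @export
fit_edpvr <- function(indices) {
  if (nrow(indices) < 4L) stopf("EDPVR fit needs >= 4 beats")
  edv <- indices$edv; edp <- indices$rvedp
  if (stats::sd(edv) < 1e-9) stopf("EDPVR fit: zero EDV variance across beats")
  fit <- stats::lm.fit(cbind(1, edv), edp)
  ss_res <- sum(fit$residuals^2); ss_tot <- sum((edp - mean(edp))^2)
  structure(list(slope = as.numeric(fit$coefficients[2L]),
                 intercept = as.numeric(fit$coefficients[1L]),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "edpvr_fit")
}

#' Beats to hemodynamic recovery after occlusion release
#'
#' Counts post-occlusion beats until per-beat RVSP first returns to
#' `recovery_fraction` of the pre-occlusion baseline; a slower recovery
#' (more beats) indicates an impaired response to the preload perturbation.
#'
#' @param w a [pv_waveform].
#' @param run a `vco_run` from [detect_occlusion].
#' @param beats the `pv_beats` frame the run refers to.
#' @param recovery_fraction fraction of baseline RVSP defining recovery
#'   (default 0.95).
#' @return integer beat count, or `NA` with a warning if RVSP never
#'   recovers within the recording.
#' @export
recovery_beats <- function(w, run, beats, recovery_fraction = 0.95) {
  last_row <- run$beat_rows[length(run$beat_rows)]
  post <- beats[beats$start_idx > beats$start_idx[last_row], , drop = FALSE]
  if (!nrow(post)) stopf("no beats after the occlusion run")
  rvsp <- vapply(seq_len(nrow(post)), function(k)
    max(w$pressure[post$start_idx[k]:(post$end_idx[k] - 1L)]), numeric(1L))
  hit <- which(rvsp >= recovery_fraction * run$baseline_rvsp)
  if (!length(hit)) {
    warnf("RVSP never recovered to %.0f%% of baseline within the recording",
          100 * recovery_fraction)
    return(NA_integer_)
  }
  hit[1L]
}
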