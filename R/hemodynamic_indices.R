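#' Pressure-volume loop area (stroke work)
#'
#' Absolute shoelace area of the closed `(V, P)` polygon formed by one
#' cardiac cycle (the last-to-first edge is implied). For a counterclockwise
#' murine RV loop this is the stroke work in uL mmHg.
#'
#' @param pressure_cycle pressure samples of one cycle, mmHg.
#' @param volume_cycle volume samples, uL; same length, >= 3 samples.
#' @return area in uL mmHg (>= 0).
#' @examples
#' loop_area(c(25, 25, 5, 5), c(10, 20, 20, 10)) # 10 x 20 rectangle = 200
#' @export
loop_area <- function(pressure_cycle, volume_cycle) {
  n <- length(pressure_cycle)
  if (n < 3L || length(volume_cycle) != n)
    stopf("need >= 3 paired samples to form a loop")
  x <- volume_cycle; y <- pressure_cycle
  j <- c(n, seq_len(n - 1L)) # previous vertex, wrapping
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Isovolumic relaxation time constant tau
#'
#' Fits the pressure decay from dP/dt-min to the end of isovolumic
#' relaxation. The fit window runs from the beat's dP/dt-min sample to the
#' first sample where pressure drops to `max(next RVEDP, 10% of RVSP)`.
#' Two standard estimators:
#' \describe{
#'   \item{weiss}{zero-asymptote mono-exponential: least-squares line on
#'     `ln P` vs `t`, `tau = -1/slope`.}
#'   \item{glantz}{nonlinear `P(t) = Pinf + (P0 - Pinf) exp(-t/tau)` with a
#'     free asymptote `Pinf`, robust when pressures approach zero.}
#' }
#' If the weiss window contains non-positive pressures the fit falls back to
#' glantz with a warning.
#'
#' @param w a [pv_waveform].
#' @param beat one row of a `pv_beats` frame.
#' @param method `"weiss"` (default) or `"glantz"`.
#' @return `tau` in ms; for glantz the asymptote is attached as attribute
#'   `"p_inf"` (mmHg).
#' @export
fit_tau <- function(w, beat, method = c("weiss", "glantz")) {
  method <- match.arg(method)
  i0 <- beat$dpdt_min_idx[1L]
  i_end <- beat$end_idx[1L] - 1L
  if (is.na(i0) || i0 >= i_end) stopf("beat has no relaxation window")
  span_all <- i0:i_end
  rvsp <- max(w$pressure[beat$start_idx[1L]:i_end])
  edp_next <- w$pressure[beat$end_idx[1L]]
  floor_p <- max(edp_next, 0.10 * rvsp)
  below <- which(w$pressure[span_all] <= floor_p)
  i1 <- if (length(below)) span_all[below[1L]] else i_end
  span <- i0:i1
  if (length(span) < 5L)
    stopf("relaxation window too short (%d samples, need >= 5)", length(span))
  tt <- w$time[span] - w$time[span[1L]]
  pp <- w$pressure[span]
  if (method == "weiss") {
    if (any(pp <= 0)) {
      warnf("non-positive pressures in weiss window; falling back to glantz")
      return(fit_tau(w, beat, method = "glantz"))
    }
    fit <- stats::lm.fit(cbind(1, tt), log(pp))
    slope <- fit$coefficients[2L]
    if (!is.finite(slope) || slope >= 0) stopf("weiss fit: non-decaying pressure")
    return(as.numeric(-1 / slope) * 1000)
  }
  # glantz: seed from a weiss-style fit on offset-corrected pressures
  p_inf0 <- min(pp) - 0.05 * abs(min(pp))
  tau0 <- tryCatch({
    f <- stats::lm.fit(cbind(1, tt), log(pmax(pp - p_inf0, 1e-6)))
    max(-1 / f$coefficients[2L], 1e-4)
  }, error = function(e) 0.005)
  fit <- minpack.lm::nlsLM(pp ~ p_inf + (p0 - p_inf) * exp(-tt / tau),
                           start = list(p_inf = p_inf0, p0 = pp[1L], tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(as.numeric(co[["tau"]]) * 1000, p_inf = as.numeric(co[["p_inf"]]))
}

#' Per-beat scalar hemodynamic indices
#'
#' Extracts the standard steady-state indices from one segmented beat:
#' RVSP (peak systolic pressure), RVEDP (pressure at end-diastole), minimum
#' diastolic pressure, pulse pressure, end-diastolic / end-systolic volumes
#' (max / min volume within the beat, robust to small P-V phase offsets),
#' stroke volume, ejection fraction, stroke work ([loop_area]), end-systolic
#' pressure, dP/dt extremes, tau ([fit_tau]) and the RR interval. A failed
#' tau fit yields `NA` with a warning rather than a record failure.
#'
#' @param w a [pv_waveform].
#' @param beat one row of a `pv_beats` frame.
#' @param tau_method passed to [fit_tau].
#' @param pp_def pulse-pressure definition: `"min_diastolic"` (RVSP minus
#'   minimum diastolic pressure, default) or `"edp"` (RVSP minus RVEDP).
#' @param smooth_ms window (ms) of quadratic smoothing applied to the
#'   beat's pressure and volume before extrema are read off, so catheter
#'   noise does not inflate max/min-based indices; 0 disables. The tau fit
#'   always uses the raw pressure.
#' @return one-row data.frame of class `beat_indices`.
#' @export
beat_indices <- function(w, beat, tau_method = "weiss",
                         pp_def = c("min_diastolic", "edp"), smooth_ms = 5) {
  pp_def <- match.arg(pp_def)
  span <- beat$start_idx[1L]:(beat$end_idx[1L] - 1L)
  p <- w$pressure[span]; v <- w$volume[span]
  sr <- w$sampling_rate
  if (smooth_ms > 0 && length(span) >= 9L) {
    n_w <- max(5L, round(smooth_ms * sr / 1000))
    p <- sg_smooth(p, n_w)
    v <- sg_smooth(v, n_w)
  }
  dpdt <- smooth_derivative(w$pressure, sr)[span]
  rvsp <- max(p)
  rvedp <- p[beat$ed_idx[1L] - beat$start_idx[1L] + 1L]
  pmin_d <- min(p)
  edv <- max(v); esv <- min(v); sv <- edv - esv
  es_off <- beat$es_idx[1L] - beat$start_idx[1L] + 1L
  esp <- if (!is.na(es_off) && es_off >= 1L && es_off <= length(p))
    p[es_off] else NA_real_
  tau <- tryCatch(as.numeric(fit_tau(w, beat, method = tau_method)),
                  error = function(e) {
                    warnf("tau fit failed for beat at sample %d: %s",
                          beat$start_idx[1L], conditionMessage(e))
                    NA_real_
                  })
  structure(data.frame(
    rvsp = rvsp, rvedp = rvedp, pmin = pmin_d,
    pp = if (pp_def == "min_diastolic") rvsp - pmin_d else rvsp - rvedp,
    edv = edv, esv = esv, sv = sv,
    ef = if (edv > 0) sv / edv else NA_real_,
    esp = esp,
    sw = loop_area(p, v),
    dpdt_max = max(dpdt), dpdt_min = min(dpdt),
    tau = tau, rr = beat$rr_ms[1L]),
    class = c("beat_indices", "data.frame"))
}

#' Stroke-work density
#'
#' Stroke work per RV free-wall tissue volume, assuming a uniform tissue
#' density (1.053 g/mL by default): `sw / (rv_mass / tissue_density)`,
#' reported in mmHg/beat.
#'
#' @param sw stroke work, uL mmHg.
#' @param rv_mass RV free-wall mass, mg.
#' @param tissue_density tissue density, mg/uL (g/mL).
#' @return SW density, mmHg/beat.
#' @examples
#' sw_density(1500, 25) # ~ 63.2 mmHg/beat
#' @export
sw_density <- function(sw, rv_mass, tissue_density = 1.053) {
  if (any(rv_mass <= 0)) stopf("rv_mass must be positive")
  sw / (rv_mass / tissue_density)
}

#' Fulton index of right-ventricular hypertrophy
#'
#' Weight ratio of the RV free wall to the left ventricle plus septum.
#'
#' @param rv_mass RV free-wall mass, mg.
#' @param lvs_mass LV + septum mass, mg.
#' @return dimensionless ratio (mg/mg).
#' @examples
#' fulton_index(20, 80) # 0.25
#' @export
fulton_index <- function(rv_mass, lvs_mass) {
  if (any(rv_mass <= 0) || any(lvs_mass <= 0))
    stopf("masses must be positive")
  rv_mass / lvs_mass
}

#' Aggregate per-beat indices into one animal's hemodynamic record
#'
#' Averages the per-beat indices over the steady window (mean of per-beat
#' ratios, e.g. mean per-beat EF) and derives the rate- and afterload-level
#' quantities: heart rate `hr = 60000 / mean(rr)` (beats/min), cardiac
#' output `co = mean(sv) * hr` (uL/min), total pulmonary vascular resistance
#' `tpvr = mean(rvsp) / co` with CO in mL/min (mmHg min/mL), chamber
#' compliance `mean(sv) / mean(pp)` (uL/mmHg), effective arterial elastance
#' `ea = mean(esp) / mean(sv)` (mmHg/uL) using the pressure at the detected
#' end-systolic point, and coupling efficiency `eta = ees / ea`. Morphometry
#' and biochemistry from the animal row are merged in (Fulton index, SW
#' density, PYD/OHP ratio).
#'
#' @param indices data.frame of per-beat indices ([beat_indices] rows).
#' @param animal optional one-row animal-table entry (see
#'   [read_animal_table]).
#' @param ees,prsw optional load-independent fits from [fit_espvr] /
#'   [fit_prsw] (numeric; `NA` if unavailable).
#' @return one-row data.frame of class `hemodynamic_record`.
#' @export
aggregate_record <- function(indices, animal = NULL, ees = NA_real_,
                             prsw = NA_real_) {
  if (nrow(indices) < 10L)
    warnf("aggregating %d beats; at least 10 consecutive clean beats are recommended",
          nrow(indices))
  m <- function(x) mean(x, na.rm = TRUE)
  hr <- 60000 / m(indices$rr)
  sv <- m(indices$sv)
  co <- sv * hr
  rvsp <- m(indices$rvsp)
  esp <- m(indices$esp)
  ea <- if (is.finite(esp) && sv > 0) esp / sv else NA_real_
  rec <- data.frame(
    subject_id = animal$subject_id %||% NA_character_,
    group_label = animal$group_label %||% NA_character_,
    hr = hr, rvsp = rvsp, rvedp = m(indices$rvedp), pp = m(indices$pp),
    edv = m(indices$edv), esv = m(indices$esv), sv = sv, ef = m(indices$ef),
    sw = m(indices$sw), co = co,
    tpvr = rvsp / (co / 1000),
    compliance = sv / m(indices$pp),
    ea = ea, ees = ees, prsw = prsw,
    eta = if (is.finite(ees) && is.finite(ea)) ees / ea else NA_real_,
    dpdt_max = m(indices$dpdt_max), dpdt_min = m(indices$dpdt_min),
    tau = m(indices$tau), esp = esp, n_beats = nrow(indices))
  if (!is.null(animal)) {
    rv <- animal$rv_mass %||% NA_real_
    lvs <- animal$lvs_mass %||% NA_real_
    ohp <- animal$ohp %||% NA_real_
    pyd <- animal$pyd %||% NA_real_
    rec$rv_mass <- rv
    rec$lvs_mass <- lvs
    rec$body_weight <- animal$body_weight %||% NA_real_
    rec$hematocrit <- animal$hematocrit %||% NA_real_
    rec$fulton <- if (is.finite(rv) && is.finite(lvs)) fulton_index(rv, lvs) else NA_real_
    rec$sw_density <- if (is.finite(rv)) sw_density(rec$sw, rv) else NA_real_
    rec$ohp <- ohp
    rec$pyd <- pyd
    rec$pyd_ohp_ratio <- if (is.finite(pyd) && is.finite(ohp) && ohp > 0)
      pyd / ohp else NA_real_
  }
  class(rec) <- c("hemodynamic_record", "data.frame")
  rec
}
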