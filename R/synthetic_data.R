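#' Normalized time-varying elastance activation
#'
#' Double-Hill activation waveform used by the ventricle simulator: a rising
#' Hill term (exponent `n1`) multiplied by a falling Hill term (exponent
#' `n2`). The half-activation time of the rising term is tied to `t_peak`,
#' and the falling term's half-time is solved in closed form so that the
#' product attains its maximum exactly at `t_peak`; the curve is then scaled
#' so the maximum is exactly 1. At `t_frac = 0` the activation is exactly 0.
#'
#' @param t_frac time within the cycle as a fraction in `[0, 1)`; vectorized.
#' @param activation list with `t_peak` (fraction of the cycle at which
#'   elastance peaks), `n1` (rise exponent), `n2` (decay exponent).
#' @return values in `[0, 1]`, same length as `t_frac`.
#' @examples
#' tf <- seq(0, 0.999, length.out = 200)
#' en <- normalized_elastance(tf, list(t_peak = 0.32, n1 = 1.9, n2 = 21.9))
#' range(en)
#' @export
normalized_elastance <- function(t_frac, activation) {
  a <- activation_shape(activation)
  x1 <- (t_frac / a$a1)^a$n1
  h <- (x1 / (1 + x1)) / (1 + (t_frac / a$a2)^a$n2)
  h / a$peak_value
}

# Resolve the double-Hill shape constants for a given activation spec.
# a1 is tied to t_peak; a2 comes from the stationarity condition at t_peak:
#   n1 / (1 + (t_peak/a1)^n1) = n2 * u / (1 + u),  u = (t_peak/a2)^n2
# which gives u = r / (n2 - r) in closed form.
activation_shape <- function(activation) {
  t_peak <- activation$t_peak %||% 0.32
  n1 <- activation$n1 %||% 1.9
  n2 <- activation$n2 %||% 21.9
  if (t_peak <= 0 || t_peak >= 1) stopf("t_peak must lie in (0, 1)")
  a1 <- 0.6 * t_peak
  r <- n1 / (1 + (t_peak / a1)^n1)
  if (r >= n2) stopf("activation exponents infeasible: need n2 > %.3f", r)
  u <- r / (n2 - r)
  a2 <- t_peak / u^(1 / n2)
  x1p <- (t_peak / a1)^n1
  peak <- (x1p / (1 + x1p)) / (1 + u)
  list(t_peak = t_peak, n1 = n1, n2 = n2, a1 = a1, a2 = a2, peak_value = peak)
}

#' Parameter set for the synthetic ventricle-afterload simulator
#'
#' Ground-truth parameters for a time-varying elastance ventricle coupled to
#' a two-element proximal/distal Windkessel afterload and a resistive venous
#' inflow. Defaults approximate a healthy (normoxic) mouse right ventricle.
#'
#' @param emax end-systolic (peak) elastance, mmHg/uL; ground truth for Ees.
#' @param emin diastolic elastance, mmHg/uL (reciprocal of diastolic chamber
#'   compliance).
#' @param v0 unstressed volume, uL.
#' @param hr heart rate, beats/min.
#' @param activation list(t_peak, n1, n2), see [normalized_elastance].
#' @param afterload list(rc, rp, c): proximal resistance (mmHg s/uL), distal
#'   resistance (mmHg s/uL), arterial compliance (uL/mmHg).
#' @param preload list(p_ven, r_in): venous filling pressure (mmHg) and
#'   inflow resistance (mmHg s/uL).
#' @param noise list(sd_p, sd_v): SD of additive Gaussian measurement noise
#'   on pressure (mmHg) and volume (uL), applied after integration.
#' @param seed integer seed for the noise draws (NULL = use current RNG).
#' @return validated list of class `elastance_params`.
#' @export
elastance_params <- function(emax = 2.6, emin = 0.038, v0 = 3, hr = 552,
                             activation = list(t_peak = 0.32, n1 = 1.9, n2 = 10),
                             afterload = list(rc = 0.02, rp = 0.085, c = 0.8),
                             preload = list(p_ven = 4.83, r_in = 0.015),
                             noise = list(sd_p = 0.5, sd_v = 0.3),
                             seed = NULL) {
  p <- structure(list(emax = emax, emin = emin, v0 = v0, hr = hr,
                      activation = activation, afterload = afterload,
                      preload = preload, noise = noise, seed = seed),
                 class = "elastance_params")
  validate_elastance_params(p)
  p
}

validate_elastance_params <- function(p) {
  if (!(p$emax > p$emin && p$emin > 0))
    stopf("need emax > emin > 0 (got emax=%g, emin=%g)", p$emax, p$emin)
  if (p$hr <= 0) stopf("hr must be positive")
  for (nm in c("rc", "rp", "c")) if (p$afterload[[nm]] <= 0)
    stopf("afterload$%s must be positive", nm)
  for (nm in c("p_ven", "r_in")) if (p$preload[[nm]] <= 0)
    stopf("preload$%s must be positive", nm)
  if (p$noise$sd_p < 0 || p$noise$sd_v < 0) stopf("noise SDs must be >= 0")
  invisible(p)
}

# Run the RNG-dependent part of a simulation under a local seed, leaving the
# caller's RNG state untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Core integrator: time-varying elastance ventricle with diode inflow and a
# proximal-resistance + RC Windkessel outflow, advanced by classical RK4.
# p_ven may be a scalar or a per-step vector (held constant within a step).
# Returns clean pressure/volume/arterial-pressure sample paths.
integrate_pv <- function(p, n_steps, dt, p_ven_vec, v_init = NULL, pa_init = NULL) {
  act <- activation_shape(p$activation)
  period <- 60 / p$hr
  emin <- p$emin; emax <- p$emax; v0 <- p$v0
  rc <- p$afterload$rc; rp <- p$afterload$rp; ca <- p$afterload$c
  r_in <- p$preload$r_in
  a1 <- act$a1; a2 <- act$a2; n1 <- act$n1; n2 <- act$n2; pk <- act$peak_value

  en_at <- function(tt) {
    tf <- tt %% period / period
    x1 <- (tf / a1)^n1
    ((x1 / (1 + x1)) / (1 + (tf / a2)^n2)) / pk
  }
  if (length(p_ven_vec) == 1L) p_ven_vec <- rep(p_ven_vec, n_steps)

  V <- numeric(n_steps); Pa <- numeric(n_steps); P <- numeric(n_steps)
  E <- numeric(n_steps)
  V[1L] <- v_init %||% (v0 + 0.8 * p_ven_vec[1L] / emin)
  Pa[1L] <- pa_init %||% (3 * p_ven_vec[1L])

  rhs <- function(tt, v, pa, pv) {
    e <- emin + (emax - emin) * en_at(tt)
    pr <- e * (v - v0)
    qin <- (pv - pr) / r_in
    if (qin < 0) qin <- 0
    qout <- (pr - pa) / rc
    if (qout < 0) qout <- 0
    c(qin - qout, (qout - pa / rp) / ca)
  }

  for (i in seq_len(n_steps)) {
    tt <- (i - 1L) * dt
    pv <- p_ven_vec[i]
    e <- emin + (emax - emin) * en_at(tt)
    E[i] <- e
    P[i] <- e * (V[i] - v0)
    if (i == n_steps) break
    k1 <- rhs(tt, V[i], Pa[i], pv)
    k2 <- rhs(tt + dt / 2, V[i] + dt / 2 * k1[1L], Pa[i] + dt / 2 * k1[2L], pv)
    k3 <- rhs(tt + dt / 2, V[i] + dt / 2 * k2[1L], Pa[i] + dt / 2 * k2[2L], pv)
    k4 <- rhs(tt + dt, V[i] + dt * k3[1L], Pa[i] + dt * k3[2L], pv)
    V[i + 1L] <- V[i] + dt / 6 * (k1[1L] + 2 * k2[1L] + 2 * k3[1L] + k4[1L])
    Pa[i + 1L] <- Pa[i] + dt / 6 * (k1[2L] + 2 * k2[2L] + 2 * k3[2L] + k4[2L])
    if (V[i + 1L] <= 0)
      stopf("unstable integration: volume <= 0 at t=%.3f s (check v0/preload)", tt)
    if (P[i] > 500)
      stopf("unstable integration: pressure > 500 mmHg at t=%.3f s (check emax/afterload)", tt)
  }
  list(V = V, Pa = Pa, P = P, E = E, period = period)
}

# Per-beat ground truth from the clean sample paths: beats delimited by the
# integration phase (multiples of the cycle period), not by detection.
truth_per_beat <- function(sim, dt, n_steps) {
  period <- sim$period
  beat_of <- pmin(floor(((seq_len(n_steps) - 1L) * dt) / period) + 1L,
                  ceiling(n_steps * dt / period))
  beats <- sort(unique(beat_of))
  rows <- lapply(beats, function(b) {
    idx <- which(beat_of == b)
    if (length(idx) < 5L) return(NULL)
    v <- sim$V[idx]; pr <- sim$P[idx]
    data.frame(beat = b, start_idx = idx[1L], end_idx = idx[length(idx)],
               edv = max(v), esv = min(v), sv = max(v) - min(v),
               sw = loop_area(pr, v))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
}

#' Simulate steady-state right-ventricular pressure-volume beats
#'
#' Forward-integrates the elastance-Windkessel model of [elastance_params]
#' with classical 4th-order Runge-Kutta stepping at `dt`. Instantaneous
#' ventricular pressure is `P = E(t) (V - v0)` with
#' `E(t) = emin + (emax - emin) e_n(t)`; filling is resistive from the venous
#' pressure when `p_ven > P`, ejection into the Windkessel when `P > P_art`,
#' and both valves are closed otherwise. A configurable number of initial
#' beats is integrated and discarded so the recording starts in periodic
#' steady state. Seeded Gaussian measurement noise is added after
#' integration.
#'
#' @param params an [elastance_params] object.
#' @param n_beats number of cardiac cycles to record.
#' @param dt sample interval, s (default 0.001, i.e. 1000 Hz).
#' @param transient_beats cycles integrated and discarded before recording.
#' @param subject_id,group_label metadata for the returned waveform.
#' @return A [pv_waveform] with attribute `"truth"`: a list with the true
#'   `emax`, `emin`, `v0`, `hr`, a per-beat data.frame (`edv`, `esv`, `sv`,
#'   `sw` from the noise-free signals), and the elastance trace `e_t`.
#' @examples
#' w <- simulate_beats(elastance_params(seed = 1), n_beats = 4)
#' attr(w, "truth")$per_beat
#' @export
simulate_beats <- function(params, n_beats = 10, dt = 0.001,
                           transient_beats = 16, subject_id = "sim",
                           group_label = "sim") {
  validate_elastance_params(params)
  period <- 60 / params$hr
  n_trans <- ceiling(transient_beats * period / dt)
  n_rec <- ceiling(n_beats * period / dt)
  sim <- integrate_pv(params, n_trans + n_rec, dt, params$preload$p_ven)
  keep <- (n_trans + 1L):(n_trans + n_rec)
  # re-zero phase so recorded samples start at a cycle boundary
  shift <- keep[1L] - 1L
  clean <- list(V = sim$V[keep], Pa = sim$Pa[keep], P = sim$P[keep],
                E = sim$E[keep], period = period)
  truth <- list(emax = params$emax, emin = params$emin, v0 = params$v0,
                hr = params$hr, e_t = clean$E,
                per_beat = truth_per_beat(clean, dt, length(keep)))
  noise <- with_seed(params$seed, list(
    p = stats::rnorm(n_rec, 0, params$noise$sd_p),
    v = stats::rnorm(n_rec, 0, params$noise$sd_v)))
  w <- pv_waveform(time = (seq_len(n_rec) - 1L) * dt,
                   pressure = clean$P + noise$p,
                   volume = pmax(clean$V + noise$v, 0.5),
                   subject_id = subject_id, group_label = group_label,
                   sampling_rate = 1 / dt)
  attr(w, "truth") <- truth
  w
}

#' Simulate a vena-cava occlusion (VCO) maneuver
#'
#' Starts from periodic steady state, records `pre_beats` baseline cycles,
#' ramps the venous pressure down linearly by `ramp_depth` of baseline over
#' `ramp_beats` cycles, holds it for `hold_beats` cycles, then releases it
#' with a first-order venous refill time constant `refill_tau`, recording
#' `post_beats` further cycles. The occlusion sweeps preload downward so the
#' end-systolic points of successive beats trace out the end-systolic
#' pressure-volume relation with true slope `emax` and intercept `v0`.
#'
#' @inheritParams simulate_beats
#' @param ramp_beats cycles over which venous pressure falls.
#' @param ramp_depth fractional reduction of venous pressure in `(0, 1]`
#'   (0 is allowed and yields a plain steady recording).
#' @param pre_beats,hold_beats,post_beats baseline, hold and recovery cycles.
#' @param refill_tau venous refill time constant, s.
#' @return A [pv_waveform]; attribute `"truth"` additionally carries
#'   `occluded_beats` (1-based beat numbers of the ramp + hold phase) and the
#'   per-step venous pressure schedule `p_ven_t`.
#' @export
simulate_vco <- function(params, ramp_beats = 10, ramp_depth = 0.6,
                         pre_beats = 12, hold_beats = 2, post_beats = 12,
                         refill_tau = 0.25, dt = 0.001, transient_beats = 16,
                         subject_id = "sim_vco", group_label = "sim") {
  validate_elastance_params(params)
  if (ramp_depth < 0 || ramp_depth > 1)
    stopf("ramp_depth must lie in [0, 1]")
  period <- 60 / params$hr
  n_per <- period / dt
  total_beats <- pre_beats + ramp_beats + hold_beats + post_beats
  n_trans <- ceiling(transient_beats * n_per)
  n_rec <- ceiling(total_beats * n_per)
  pv0 <- params$preload$p_ven
  t_rec <- (seq_len(n_rec) - 1L) * dt
  t_ramp0 <- pre_beats * period
  t_hold0 <- (pre_beats + ramp_beats) * period
  t_rel <- (pre_beats + ramp_beats + hold_beats) * period
  pv_low <- pv0 * (1 - ramp_depth)
  pven <- ifelse(t_rec < t_ramp0, pv0,
          ifelse(t_rec < t_hold0,
                 pv0 - (pv0 - pv_low) * (t_rec - t_ramp0) / (t_hold0 - t_ramp0),
          ifelse(t_rec < t_rel, pv_low,
                 pv0 - (pv0 - pv_low) * exp(-(t_rec - t_rel) / refill_tau))))
  sim <- integrate_pv(params, n_trans + n_rec, dt,
                      c(rep(pv0, n_trans), pven))
  keep <- (n_trans + 1L):(n_trans + n_rec)
  clean <- list(V = sim$V[keep], Pa = sim$Pa[keep], P = sim$P[keep],
                E = sim$E[keep], period = period)
  occluded <- if (ramp_depth > 0)
    (pre_beats + 1L):(pre_beats + ramp_beats + hold_beats) else integer(0)
  truth <- list(emax = params$emax, emin = params$emin, v0 = params$v0,
                hr = params$hr, e_t = clean$E, p_ven_t = pven,
                occluded_beats = occluded,
                per_beat = truth_per_beat(clean, dt, length(keep)))
  noise <- with_seed(params$seed, list(
    p = stats::rnorm(n_rec, 0, params$noise$sd_p),
    v = stats::rnorm(n_rec, 0, params$noise$sd_v)))
  w <- pv_waveform(time = t_rec,
                   pressure = clean$P + noise$p,
                   volume = pmax(clean$V + noise$v, 0.5),
                   subject_id = subject_id, group_label = group_label,
                   sampling_rate = 1 / dt)
  attr(w, "truth") <- truth
  w
}
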