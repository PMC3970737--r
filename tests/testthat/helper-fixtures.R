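# Shared fixtures, built in code at test time.

# fast low-cost parameter set for unit tests
test_params <- function(..., seed = 1, noise0 = FALSE) {
  args <- list(...)
  defaults <- list(emax = 2.6, emin = 0.04, v0 = 3, hr = 570,
                   afterload = list(rc = 0.02, rp = 0.10, c = 0.7),
                   preload = list(p_ven = 4.8, r_in = 0.015),
                   noise = if (noise0) list(sd_p = 0, sd_v = 0) else
                     list(sd_p = 0.5, sd_v = 0.3),
                   seed = seed)
  do.call(elastance_params, utils::modifyList(defaults, args))
}

# a minimal hand-built waveform: mono-exponential pressure decay at constant
# volume, plus a fake beat row covering it, for tau-fit tests
decay_fixture <- function(tau_ms = 4, p0 = 30, p_inf = 0, n = 60) {
  tt <- (seq_len(n) - 1L) / 1000
  p <- p_inf + (p0 - p_inf) * exp(-tt / (tau_ms / 1000))
  w <- pv_waveform(tt, p, rep(10, n), sampling_rate = 1000)
  beat <- data.frame(start_idx = 1L, end_idx = n, ed_idx = 1L,
                     es_idx = 1L, dpdt_max_idx = 1L, dpdt_min_idx = 1L,
                     rr_ms = n - 1, extrasystolic = FALSE, in_occlusion = FALSE)
  list(w = w, beat = beat)
}

# beats frame with prescribed RR intervals (flagging only reads rr_ms)
rr_beats <- function(rr_ms) {
  n <- length(rr_ms)
  data.frame(start_idx = seq_len(n), end_idx = seq_len(n) + 1L,
             ed_idx = seq_len(n), es_idx = NA_integer_,
             dpdt_max_idx = seq_len(n), dpdt_min_idx = seq_len(n),
             rr_ms = rr_ms, extrasystolic = FALSE, in_occlusion = FALSE)
}

# a tiny two-group spec for fast end-to-end runs
small_specs <- function(n = 3) {
  sp <- default_group_specs()[c("normoxia", "hysu28")]
  sp$normoxia$n_animals <- n
  sp$hysu28$n_animals <- n
  sp
}

# published reference means for one field, in group order
ref_means <- function(field) unname(reference_field(field))
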