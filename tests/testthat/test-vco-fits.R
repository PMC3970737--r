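# build a minimal waveform + beats frame whose per-beat RVSP follows a
# prescribed sequence (100 samples per beat, triangular pressure pulses)
rvsp_series_waveform <- function(rvsp) {
  spb <- 100L
  n <- length(rvsp) * spb
  tt <- (seq_len(n) - 1) / 1000
  p <- numeric(n); v <- numeric(n)
  for (k in seq_along(rvsp)) {
    i <- ((k - 1L) * spb + 1L):(k * spb)
    ph <- seq(0, 1, length.out = spb)
    p[i] <- pmax(0.5, rvsp[k] * pmax(0, 1 - abs(ph - 0.35) / 0.3))
    v[i] <- 20 - 8 * pmax(0, 1 - abs(ph - 0.45) / 0.4)
  }
  w <- pv_waveform(tt, p, v)
  beats <- data.frame(start_idx = seq(1L, n, by = spb),
                      end_idx = c(seq(spb + 1L, n, by = spb), n),
                      ed_idx = seq(1L, n, by = spb), es_idx = NA_integer_,
                      dpdt_max_idx = seq(1L, n, by = spb) + 10L,
                      dpdt_min_idx = seq(1L, n, by = spb) + 80L,
                      rr_ms = 100, extrasystolic = FALSE, in_occlusion = FALSE)
  list(w = w, beats = beats)
}

test_that("occlusion detection finds ramps and ignores steady recordings", {
  p <- test_params(seed = 2)
  w <- simulate_vco(p, ramp_depth = 0.5)
  b <- flag_extrasystoles(segment_beats(w))
  occ <- detect_occlusion(w, b)
  expect_length(occ$runs, 1L)
  expect_gte(length(occ$runs[[1]]$beat_rows), 6L)
  expect_equal(occ$runs[[1]]$baseline_rvsp,
               max(w$pressure[1:500]), tolerance = 0.06)
  # flagged beats sit inside the simulated occlusion phase
  tru <- attr(w, "truth")
  occl_span <- range(tru$per_beat$start_idx[tru$per_beat$beat %in% tru$occluded_beats])
  flagged <- which(occ$beats$in_occlusion)
  expect_gte(min(occ$beats$start_idx[flagged]), occl_span[1] - 150)

  ws <- simulate_beats(p, n_beats = 16)
  bs <- flag_extrasystoles(segment_beats(ws))
  expect_length(detect_occlusion(ws, bs)$runs, 0L)
})

test_that("three sequential ramps yield three runs", {
  fall1 <- seq(26, 14, length.out = 7)
  rise1 <- seq(15.5, 25, length.out = 7)
  rvsp <- c(rep(26, 8) + c(-.1, .1), fall1, rise1,
            rep(26, 4), fall1, rise1, rep(26, 4), fall1, rise1, rep(26, 4))
  fx <- rvsp_series_waveform(rvsp)
  occ <- detect_occlusion(fx$w, fx$beats)
  expect_length(occ$runs, 3L)
})

test_that("ESPVR fit is exact on collinear end-systolic points", {
  # three steady beats whose ES points sit exactly on P = 2 (V - 5)
  spb <- 120L
  ves <- c(10, 15, 20)
  tt <- (seq_len(3L * spb) - 1) / 1000
  p <- numeric(0); v <- numeric(0)
  for (k in 1:3) {
    ph <- seq(0, 2 * pi, length.out = spb)
    vk <- ves[k] + 6 + 6 * cos(ph)          # min volume = ves[k]
    ek <- 2 * (0.05 + 0.95 * (sin(ph / 2)^4)) # elastance-like activation
    pk <- ek * (vk - 5)
    p <- c(p, pk); v <- c(v, vk)
  }
  w <- pv_waveform(tt, p, v)
  beats <- data.frame(start_idx = (0:2) * spb + 1L, end_idx = (1:3) * spb + 1L,
                      ed_idx = (0:2) * spb + 1L, es_idx = NA_integer_,
                      dpdt_max_idx = (0:2) * spb + 10L,
                      dpdt_min_idx = (1:3) * spb - 10L,
                      rr_ms = 120, extrasystolic = FALSE, in_occlusion = FALSE)
  beats$end_idx[3] <- 3L * spb
  run <- structure(list(beat_rows = 1:3, baseline_rvsp = max(p),
                        span = c(1L, 3L * spb)), class = "vco_run")
  # 3 beats after dropping the onset beat is too few
  expect_error(fit_espvr(w, run, beats), ">= 4")
  # append a copy of the first beat so 4 collinear ES points remain
  w2 <- pv_waveform(c(tt, tt[length(tt)] + 1e-3 + tt[1:spb]),
                    c(p, p[1:spb]), c(v, v[1:spb]))
  beats2 <- rbind(beats, beats[1, ])
  beats2$start_idx[4] <- 3L * spb + 1L
  beats2$end_idx[4] <- 4L * spb
  beats2$ed_idx[4] <- 3L * spb + 1L
  beats2$dpdt_max_idx[4] <- 3L * spb + 10L
  beats2$dpdt_min_idx[4] <- 4L * spb - 10L
  run5 <- structure(list(beat_rows = c(1L, 1:4), baseline_rvsp = max(p),
                         span = c(1L, 4L * spb)), class = "vco_run")
  f <- fit_espvr(w2, run5, beats2, tol_v0 = 1e-4)
  expect_equal(f$ees, 2.0, tolerance = 0.01)
  expect_equal(f$v0, 5.0, tolerance = 0.05)
  expect_equal(f$r2, 1.0, tolerance = 1e-4)
  expect_true(f$converged)
})

test_that("ESPVR recovers simulator contractility on a noise-free occlusion", {
  p <- test_params(emax = 2.5, v0 = 3, noise0 = TRUE)
  w <- simulate_vco(p)
  b <- flag_extrasystoles(segment_beats(w))
  occ <- detect_occlusion(w, b)
  f <- fit_espvr(w, occ$runs[[1]], occ$beats)
  expect_equal(f$ees, 2.5, tolerance = 0.02)
  expect_lt(abs(f$v0 - 3), 0.5)
  expect_gt(f$r2, 0.99)
})

test_that("ESPVR fit behaves predictably under volume-unit rescaling", {
  p <- test_params(emax = 3, v0 = 2, noise0 = TRUE)
  w <- simulate_vco(p)
  b <- flag_extrasystoles(segment_beats(w))
  occ <- detect_occlusion(w, b)
  f1 <- fit_espvr(w, occ$runs[[1]], occ$beats)
  k <- 2.5
  w2 <- pv_waveform(w$time, w$pressure, k * w$volume,
                    sampling_rate = w$sampling_rate)
  f2 <- fit_espvr(w2, occ$runs[[1]], occ$beats)
  expect_equal(f2$ees, f1$ees / k, tolerance = 0.01)
  expect_equal(f2$v0, k * f1$v0, tolerance = 0.15)
})

test_that("PRSW and EDPVR fits are exact on collinear inputs and reject degeneracy", {
  idx <- data.frame(edv = c(10, 12, 14, 16))
  idx$sw <- 5 * (idx$edv - 8)
  f <- fit_prsw(idx)
  expect_equal(f$prsw, 5.0)
  expect_equal(f$vw, 8.0)
  expect_equal(f$r2, 1.0)
  expect_error(fit_prsw(idx[1:3, ]), ">= 4")
  idx$edv <- 12
  expect_error(fit_prsw(idx), "zero EDV variance")

  idx2 <- data.frame(edv = c(10, 15, 20, 25))
  idx2$rvedp <- 0.1 * (idx2$edv - 5)
  e <- fit_edpvr(idx2)
  expect_equal(e$slope, 0.1)
  expect_equal(e$intercept, -0.5)
  idx2$rvedp <- 1.4
  expect_equal(fit_edpvr(idx2)$slope, 0)
})

test_that("PRSW is positive with near-unit r2 on a simulated occlusion", {
  p <- test_params(noise0 = TRUE)
  w <- simulate_vco(p)
  b <- flag_extrasystoles(segment_beats(w))
  occ <- detect_occlusion(w, b)
  rows <- occ$runs[[1]]$beat_rows[-1]
  idx <- do.call(rbind, lapply(rows, function(k)
    suppressWarnings(beat_indices(w, occ$beats[k, ]))))
  f <- fit_prsw(idx)
  expect_gt(f$prsw, 0)
  expect_gt(f$r2, 0.95)
  # diastolic relation slope tracks the generator's 1/compliance; the
  # dynamic EDP fiducial (read before filling fully completes) flattens the
  # slope relative to the static value
  e <- fit_edpvr(idx)
  expect_lt(abs(e$slope - p$emin) / p$emin, 0.2)
  expect_gt(e$slope, 0)
})

test_that("recovery count reads the first beat back at baseline", {
  rvsp <- c(rep(26, 8), seq(25, 13, length.out = 6),
            c(15, 17, 19, 21, 23, 24.2, 24.8, 25.5, 25.8, 26))
  fx <- rvsp_series_waveform(rvsp)
  occ <- detect_occlusion(fx$w, fx$beats)
  expect_length(occ$runs, 1L)
  run <- occ$runs[[1]]
  rb <- recovery_beats(fx$w, run, occ$beats)
  post <- which(seq_along(rvsp) > run$beat_rows[length(run$beat_rows)])
  expected <- which(rvsp[post] >= 0.95 * run$baseline_rvsp)[1]
  expect_equal(rb, expected)
  # instantaneous recovery
  rvsp2 <- c(rep(26, 8), seq(25, 13, length.out = 6), rep(26, 4))
  fx2 <- rvsp_series_waveform(rvsp2)
  occ2 <- detect_occlusion(fx2$w, fx2$beats)
  expect_equal(recovery_beats(fx2$w, occ2$runs[[1]], occ2$beats), 1L)
  # never recovers
  rvsp3 <- c(rep(26, 8), seq(25, 13, length.out = 6), rep(14, 4))
  fx3 <- rvsp_series_waveform(rvsp3)
  occ3 <- detect_occlusion(fx3$w, fx3$beats)
  expect_warning(rb3 <- recovery_beats(fx3$w, occ3$runs[[1]], occ3$beats),
                 "never recovered")
  expect_true(is.na(rb3))
})
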