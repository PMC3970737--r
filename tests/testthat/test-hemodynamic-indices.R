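test_that("loop area matches hand geometry and the integral oracle", {
  # 10x20 rectangle traversed counterclockwise in (V, P)
  expect_equal(loop_area(c(25, 25, 5, 5), c(10, 20, 20, 10)), 200)
  expect_equal(loop_area(rep(7, 5), rep(12, 5)), 0)
  expect_error(loop_area(1:2, 1:2), ">= 3")

  # independent oracle: cyclic trapezoidal integration of P dV
  trap_area <- function(p, v) {
    j <- c(seq_along(p)[-1], 1L)
    abs(sum((p + p[j]) / 2 * (v[j] - v)))
  }
  set.seed(5)
  for (i in 1:25) {
    p <- test_params(emax = runif(1, 1.5, 5), hr = runif(1, 500, 650),
                     seed = i, noise0 = TRUE)
    w <- simulate_beats(p, n_beats = 3)
    b <- segment_beats(w)
    for (k in seq_len(nrow(b))) {
      span <- b$start_idx[k]:(b$end_idx[k] - 1)
      a1 <- loop_area(w$pressure[span], w$volume[span])
      a2 <- trap_area(w$pressure[span], w$volume[span])
      expect_equal(a1, a2, tolerance = 1e-3)
    }
  }
})

test_that("tau fits recover generating constants of exponential decays", {
  fx <- decay_fixture(tau_ms = 4, p0 = 30)
  expect_equal(as.numeric(fit_tau(fx$w, fx$beat, method = "weiss")), 4,
               tolerance = 1e-6)

  # nonzero asymptote: glantz recovers tau, weiss is biased upward
  fx2 <- decay_fixture(tau_ms = 4, p0 = 30, p_inf = 2)
  tau_g <- fit_tau(fx2$w, fx2$beat, method = "glantz")
  expect_equal(as.numeric(tau_g), 4, tolerance = 0.01)
  expect_equal(attr(tau_g, "p_inf"), 2, tolerance = 0.05)
  tau_w <- as.numeric(fit_tau(fx2$w, fx2$beat, method = "weiss"))
  expect_gt(tau_w, 4.2)

  fx3 <- decay_fixture(tau_ms = 4, n = 3)
  expect_error(fit_tau(fx3$w, fx3$beat), "too short|relaxation")
})

test_that("per-beat indices satisfy their defining identities", {
  p <- test_params(noise0 = TRUE)
  w <- simulate_beats(p, n_beats = 5)
  tru <- attr(w, "truth")$per_beat
  b <- segment_beats(w)
  idx <- do.call(rbind, lapply(seq_len(nrow(b)), function(k)
    beat_indices(w, b[k, ])))
  expect_equal(idx$sv, idx$edv - idx$esv) # exact identity
  expect_true(all(idx$rvsp >= idx$rvedp))
  expect_true(all(idx$ef > 0 & idx$ef <= 1))
  expect_true(all(idx$sw >= 0))
  expect_true(all(idx$tau > 0, na.rm = TRUE))
  # against simulator ground truth
  expect_equal(mean(idx$sv), mean(tru$sv), tolerance = 0.01)
  expect_equal(mean(idx$edv), mean(tru$edv), tolerance = 0.01)
  expect_equal(mean(idx$sw), mean(tru$sw), tolerance = 0.01)
})

test_that("stroke-work density and Fulton index follow their definitions", {
  expect_equal(sw_density(1500, 25), 1500 / (25 / 1.053), tolerance = 1e-12)
  expect_equal(round(sw_density(1500, 25), 1), 63.2)
  expect_equal(sw_density(10, 10, tissue_density = 1.0), 1.0)
  expect_error(sw_density(10, 0), "positive")

  expect_equal(fulton_index(20, 80), 0.25)
  expect_equal(fulton_index(37, 37), 1.0)
  expect_error(fulton_index(-1, 10), "positive")
})

test_that("record aggregation reproduces the derived-index arithmetic", {
  # constant per-beat indices at the control group's published means
  n <- 12
  idx <- data.frame(rvsp = 26, rvedp = 0.8, pmin = 0.5, pp = 26 - 0.5,
                    edv = 23.8, esv = 9.1, sv = 14.7, ef = 14.7 / 23.8,
                    esp = 24, sw = 300, dpdt_max = 2000, dpdt_min = -2500,
                    tau = 5.7, rr = 60000 / 552)
  idx <- idx[rep(1, n), ]
  animal <- data.frame(subject_id = "m1", group_label = "normoxia",
                       rv_mass = 20.4, lvs_mass = 78.3, body_weight = 25.3,
                       hematocrit = 46, ohp = 2.2, pyd = 0.2)
  rec <- aggregate_record(idx, animal, ees = 2.6, prsw = 20)
  expect_equal(rec$co, 14.7 * 552)           # 8114.4 uL/min
  expect_equal(rec$tpvr, 26 / (14.7 * 552 / 1000), tolerance = 1e-12) # 3.20
  expect_equal(round(rec$tpvr, 2), 3.2)
  expect_equal(rec$ef, 14.7 / 23.8)          # 0.618
  expect_equal(rec$ea, 24 / 14.7)
  expect_equal(rec$eta, 2.6 / (24 / 14.7))
  expect_equal(rec$fulton, 20.4 / 78.3)
  expect_equal(rec$pyd_ohp_ratio, 0.2 / 2.2)
  expect_warning(aggregate_record(idx[1:5, ], animal), "at least 10")
})

test_that("coupling efficiency is scale invariant", {
  for (k in c(0.1, 1, 7)) {
    ea <- 1.7; ees <- 2.9
    idx <- data.frame(rvsp = 26, rvedp = 1, pmin = 0.5, pp = 25.5, edv = 24,
                      esv = 9, sv = 15, ef = 0.6, esp = ea * 15, sw = 300,
                      dpdt_max = 2000, dpdt_min = -2500, tau = 5, rr = 100)
    idx <- idx[rep(1, 10), ]
    r1 <- aggregate_record(idx, ees = ees)
    idx$esp <- k * ea * 15
    r2 <- aggregate_record(idx, ees = k * ees)
    expect_equal(r2$eta, r1$eta, tolerance = 1e-12)
  }
})

test_that("published compliance column is consistent with SV/PP to ~2 SE", {
  # SV/PP at the published group means, PP ~ RVSP for low diastolic minima
  sv <- ref_means("sv"); rvsp <- ref_means("rvsp")
  comp <- ref_means("compliance")
  se <- reference_cohort()
  se <- se[se$field == "compliance", "se"]
  expect_true(all(abs(sv / rvsp - comp) <= 2 * se))
})

test_that("afterload indices increase with distal resistance", {
  ea <- tpvr <- numeric(5)
  rps <- seq(0.08, 0.24, length.out = 5)
  for (i in seq_along(rps)) {
    p <- test_params(noise0 = TRUE,
                     afterload = list(rc = 0.02, rp = rps[i], c = 0.7))
    w <- simulate_beats(p, n_beats = 12)
    b <- flag_extrasystoles(segment_beats(w))
    st <- select_steady_window(b, 10)
    idx <- do.call(rbind, lapply(seq_len(nrow(st)), function(k)
      suppressWarnings(beat_indices(w, st[k, ]))))
    rec <- aggregate_record(idx)
    ea[i] <- rec$ea; tpvr[i] <- rec$tpvr
  }
  expect_true(all(diff(ea) > 0))
  expect_true(all(diff(tpvr) > 0))
})
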