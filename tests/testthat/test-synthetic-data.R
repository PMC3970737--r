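test_that("normalized elastance is a unit-amplitude single-peaked activation", {
  act <- list(t_peak = 0.32, n1 = 1.9, n2 = 10)
  expect_equal(normalized_elastance(0, act), 0)
  tf <- seq(0, 0.999, by = 1e-4)
  en <- normalized_elastance(tf, act)
  expect_true(all(en >= 0 & en <= 1 + 1e-12))
  expect_equal(max(en), 1, tolerance = 1e-10)
  expect_equal(tf[which.max(en)], act$t_peak, tolerance = 1e-3)
  # bounded, positive mean activation over the cycle
  expect_gt(mean(en), 0)
  expect_lt(mean(en), 1)
  # peak location tracks t_peak across shapes
  for (tp in c(0.2, 0.3, 0.4)) {
    en2 <- normalized_elastance(tf, list(t_peak = tp, n1 = 2.2, n2 = 14))
    expect_equal(tf[which.max(en2)], tp, tolerance = 1e-3)
  }
})

test_that("parameter validation rejects non-physiological settings", {
  expect_error(elastance_params(emax = 0.03, emin = 0.04), "emax > emin")
  expect_error(elastance_params(hr = -10), "hr")
  expect_error(elastance_params(afterload = list(rc = 0.02, rp = -1, c = 0.5)),
               "rp")
  expect_error(elastance_params(noise = list(sd_p = -1, sd_v = 0)), "noise")
})

test_that("steady simulation brackets control hemodynamics and is periodic", {
  specs <- default_group_specs()
  h <- specs$normoxia$hemo
  cd <- specs$normoxia$linkage$intercept +
    specs$normoxia$linkage$slope * specs$normoxia$animal$ohp
  p <- elastance_params(emax = h$emax, emin = 1 / cd, v0 = h$v0, hr = h$hr,
                        activation = list(t_peak = h$t_peak, n1 = h$n1, n2 = h$n2),
                        afterload = list(rc = h$rc, rp = h$rp, c = h$c),
                        preload = list(p_ven = h$p_ven, r_in = h$r_in),
                        noise = list(sd_p = 0, sd_v = 0))
  w <- simulate_beats(p, n_beats = 10)
  tru <- attr(w, "truth")$per_beat
  expect_true(max(w$pressure) > 20 && max(w$pressure) < 32)
  expect_true(mean(tru$sv) > 12 && mean(tru$sv) < 17)
  # periodic steady state: all 10 loops identical within 0.1%
  expect_lt(diff(range(tru$sw)) / mean(tru$sw), 0.001)
  expect_lt(diff(range(tru$edv)) / mean(tru$edv), 0.001)
  # loop inscribed in its pressure-volume bounding box
  expect_true(all(tru$sw > 0))
  expect_true(all(tru$sw <= max(w$pressure) * tru$sv))
})

test_that("identical seeds give bit-identical waveforms", {
  p <- test_params(seed = 77)
  w1 <- simulate_beats(p, n_beats = 4)
  w2 <- simulate_beats(p, n_beats = 4)
  expect_identical(w1$pressure, w2$pressure)
  expect_identical(w1$volume, w2$volume)
  w3 <- simulate_beats(test_params(seed = 78), n_beats = 4)
  expect_false(identical(w1$pressure, w3$pressure))
})

test_that("occlusion ramps sweep preload down and a null ramp is a no-op", {
  p <- test_params(noise0 = TRUE)
  w <- simulate_vco(p, ramp_beats = 8, ramp_depth = 0.5, pre_beats = 4,
                    post_beats = 4)
  tru <- attr(w, "truth")
  ramp <- tru$per_beat[tru$per_beat$beat %in% tru$occluded_beats, ]
  expect_true(all(diff(ramp$edv) < 0))
  expect_true(all(diff(ramp$sv) < 0))

  p2 <- test_params(seed = 5)
  w0 <- simulate_vco(p2, ramp_depth = 0, pre_beats = 4, ramp_beats = 3,
                     hold_beats = 1, post_beats = 2)
  wb <- simulate_beats(p2, n_beats = 10)
  n <- min(length(w0$time), length(wb$time))
  expect_equal(w0$pressure[1:n], wb$pressure[1:n], tolerance = 1e-12)
  expect_equal(w0$volume[1:n], wb$volume[1:n], tolerance = 1e-12)
  expect_length(attr(w0, "truth")$occluded_beats, 0L)
})

test_that("analysis of a simulated occlusion recovers the generator's Emax", {
  p <- test_params(emax = 3.4, v0 = 4, noise0 = TRUE, seed = 9)
  w <- simulate_vco(p)
  b <- flag_extrasystoles(segment_beats(w))
  occ <- detect_occlusion(w, b)
  f <- fit_espvr(w, occ$runs[[1]], occ$beats)
  expect_equal(f$ees, 3.4, tolerance = 0.02)
  expect_lt(abs(f$v0 - 4), 0.5)
})

test_that("recovery gets slower as venous refill slows", {
  counts <- sapply(c(0.08, 0.2, 0.5), function(rt) {
    p <- test_params(noise0 = TRUE)
    w <- simulate_vco(p, refill_tau = rt, post_beats = 20)
    b <- flag_extrasystoles(segment_beats(w))
    occ <- detect_occlusion(w, b)
    recovery_beats(w, occ$runs[[1]], occ$beats, recovery_fraction = 0.9)
  })
  expect_true(all(diff(counts) > 0))
})

test_that("cohort generation is deterministic and draws the declared structure", {
  sp <- small_specs(2)
  c1 <- generate_cohort(sp, seed = 12)
  c2 <- generate_cohort(sp, seed = 12)
  expect_identical(c1$animals, c2$animals)
  expect_identical(c1$waveforms[[1]]$pressure, c2$waveforms[[1]]$pressure)
  expect_equal(nrow(c1$animals), 4L)
  expect_length(c1$waveforms, 4L)
  # masking: assay values limited to the per-group subset
  co <- generate_cohort(seed = 31, waveforms = FALSE)
  ohp_n <- tapply(!is.na(co$animals$ohp), co$animals$group_label, sum)
  expect_true(all(ohp_n == 5))
  pyd_n <- tapply(!is.na(co$animals$pyd), co$animals$group_label, sum)
  expect_true(all(pyd_n == 4))
  # truth manifest keeps every assay value
  expect_true(all(is.finite(co$truth$ohp_true)))
})

test_that("cohort covariate draws track the reference means", {
  co <- generate_cohort(seed = 8, waveforms = FALSE)
  ref <- reference_cohort()
  for (f in c("fulton", "hematocrit", "lvs_mass", "body_weight")) {
    rf <- ref[ref$field == f, ]
    x <- switch(f, fulton = co$animals$rv_mass / co$animals$lvs_mass,
                co$animals[[f]])
    m <- tapply(x, co$animals$group_label, mean)[as.character(rf$group_label)]
    # per-animal SD is se*sqrt(n), so the group mean has SE ~ se
    expect_true(all(abs(m - rf$mean) <= 3 * rf$se), info = f)
  }
})
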