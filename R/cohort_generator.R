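#' Default four-group cohort presets
#'
#' Group specifications emulating a murine pulmonary-arterial-hypertension
#' progression cohort: a normoxic control group and three
#' hypoxia+SU5416-exposed groups of increasing exposure duration (14, 21,
#' 28 days), with group sizes 8/9/9/8. Morphometry and biochemistry
#' (LV+septum mass, body weight, hematocrit, Fulton index, collagen OHP,
#' cross-link PYD, aortic pressure) are drawn from group normal
#' distributions whose means and SDs reproduce the published group
#' mean +/- SE structure (SD = SE * sqrt(n)). The hemodynamic generator
#' parameters (end-systolic elastance, distal resistance, arterial
#' compliance, venous pressure, heart rate) are calibrated so that the
#' *analyzed* group means of RVSP, stroke volume and heart rate land on the
#' published values: afterload resistance rises monotonically with exposure
#' severity while contractility rises early and then plateaus.
#'
#' Diastolic stiffness is mechanistically linked to fibrosis: each animal's
#' diastolic compliance is `linkage$intercept + linkage$slope * OHP` plus
#' noise (uL/mmHg), and `emin` is its reciprocal, so collagen content and
#' analyzed chamber compliance are negatively correlated across the cohort.
#' OHP/PYD assays are only available for a subset of animals per group
#' (`ohp_n`, `pyd_n`), mirroring destructive-assay sample sizes.
#'
#' @return named list of four `group_spec` lists (fields: `group_label`,
#'   `n_animals`, `hemo`, `animal`, `linkage`).
#' @export
default_group_specs <- function() {
  linkage <- list(intercept = 28.5, slope = -1.53, noise_sd = 1.0)
  spec <- function(label, n, hemo, animal)
    structure(list(group_label = label, n_animals = n, hemo = hemo,
                   animal = animal, linkage = linkage),
              class = "group_spec")
  # per-animal SDs for drawn covariates are SE * sqrt(n) of the target table
  list(
    normoxia = spec("normoxia", 8,
      hemo = list(emax = 2.6, emax_cv = 0.04, rp = 0.085, rp_cv = 0.05,
                  p_ven = 4.83, p_ven_cv = 0.04, rc = 0.02, c = 0.80,
                  r_in = 0.015, hr = 552, hr_sd = 45, v0 = 3,
                  t_peak = 0.32, n1 = 1.9, n2 = 10,
                  sd_p = 0.5, sd_v = 0.3),
      animal = list(lvs = 78.3, lvs_sd = 6.2, fulton = 0.26, fulton_sd = 0.028,
                    bw = 25.3, bw_sd = 1.7, hct = 46, hct_sd = 3.1,
                    ohp = 2.2, ohp_sd = 0.45, ohp_n = 5,
                    pyd = 0.20, pyd_sd = 0.10, pyd_n = 4,
                    aop = 53, aop_sd = 14)),
    hysu14 = spec("hysu14", 9,
      hemo = list(emax = 4.0, emax_cv = 0.04, rp = 0.133, rp_cv = 0.05,
                  p_ven = 5.59, p_ven_cv = 0.04, rc = 0.02, c = 0.60,
                  r_in = 0.015, hr = 597, hr_sd = 51, v0 = 3,
                  t_peak = 0.32, n1 = 1.9, n2 = 10,
                  sd_p = 0.5, sd_v = 0.3),
      animal = list(lvs = 77.8, lvs_sd = 12.9, fulton = 0.40, fulton_sd = 0.06,
                    bw = 23.2, bw_sd = 1.2, hct = 75, hct_sd = 6.6,
                    ohp = 5.4, ohp_sd = 0.67, ohp_n = 5,
                    pyd = 0.10, pyd_sd = 0.04, pyd_n = 4,
                    aop = 55, aop_sd = 9)),
    hysu21 = spec("hysu21", 9,
      hemo = list(emax = 4.1, emax_cv = 0.04, rp = 0.173, rp_cv = 0.05,
                  p_ven = 5.48, p_ven_cv = 0.04, rc = 0.02, c = 0.50,
                  r_in = 0.015, hr = 591, hr_sd = 57, v0 = 3,
                  t_peak = 0.32, n1 = 1.9, n2 = 10,
                  sd_p = 0.5, sd_v = 0.3),
      animal = list(lvs = 79.5, lvs_sd = 7.8, fulton = 0.43, fulton_sd = 0.03,
                    bw = 23.2, bw_sd = 2.7, hct = 74, hct_sd = 3.6,
                    ohp = 5.3, ohp_sd = 1.34, ohp_n = 5,
                    pyd = 0.08, pyd_sd = 0.02, pyd_n = 4,
                    aop = 59, aop_sd = 3)),
    hysu28 = spec("hysu28", 8,
      hemo = list(emax = 4.2, emax_cv = 0.04, rp = 0.218, rp_cv = 0.05,
                  p_ven = 5.49, p_ven_cv = 0.04, rc = 0.02, c = 0.45,
                  r_in = 0.015, hr = 597, hr_sd = 48, v0 = 3,
                  t_peak = 0.32, n1 = 1.9, n2 = 10,
                  sd_p = 0.5, sd_v = 0.3),
      animal = list(lvs = 78.9, lvs_sd = 12.7, fulton = 0.44, fulton_sd = 0.085,
                    bw = 24.1, bw_sd = 1.7, hct = 61, hct_sd = 1.1,
                    ohp = 7.1, ohp_sd = 1.12, ohp_n = 5,
                    pyd = 0.16, pyd_sd = 0.08, pyd_n = 4,
                    aop = 55, aop_sd = 3)))
}

#' Read group specifications from a YAML preset file
#'
#' The packaged preset (`system.file("extdata", "presets.yaml",
#' package = "pvloops")`) encodes [default_group_specs] on disk; custom
#' cohorts follow the same layout.
#'
#' @param path YAML file with one entry per group.
#' @return named list of `group_spec` lists.
#' @export
read_group_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s)
    structure(list(group_label = s$group_label, n_animals = s$n_animals,
                   hemo = s$hemo, animal = s$animal, linkage = s$linkage),
              class = "group_spec"))
}

# Draw one animal's generator parameters + covariates from its group spec.
draw_animal <- function(spec, subject_id, sim_seed) {
  h <- spec$hemo; a <- spec$animal; L <- spec$linkage
  for (attempt in seq_len(100L)) {
    ohp_true <- stats::rnorm(1, a$ohp, a$ohp_sd)
    cd <- L$intercept + L$slope * ohp_true + stats::rnorm(1, 0, L$noise_sd)
    hct <- stats::rnorm(1, a$hct, a$hct_sd)
    fulton <- stats::rnorm(1, a$fulton, a$fulton_sd)
    lvs <- stats::rnorm(1, a$lvs, a$lvs_sd)
    hr <- stats::rnorm(1, h$hr, h$hr_sd)
    ok <- ohp_true > 0 && cd > 5 && hct > 0 && hct < 100 &&
      fulton > 0.05 && lvs > 10 && hr > 300
    if (ok) break
    if (attempt == 100L) stopf("infeasible draws for group %s", spec$group_label)
  }
  params <- elastance_params(
    emax = h$emax * exp(stats::rnorm(1, 0, h$emax_cv)),
    emin = 1 / cd, v0 = h$v0, hr = hr,
    activation = list(t_peak = h$t_peak, n1 = h$n1, n2 = h$n2),
    afterload = list(rc = h$rc,
                     rp = h$rp * exp(stats::rnorm(1, 0, h$rp_cv)),
                     c = h$c),
    preload = list(p_ven = h$p_ven * exp(stats::rnorm(1, 0, h$p_ven_cv)),
                   r_in = h$r_in),
    noise = list(sd_p = h$sd_p, sd_v = h$sd_v),
    seed = sim_seed)
  list(params = params,
       animal = data.frame(
         subject_id = subject_id, group_label = spec$group_label,
         rv_mass = fulton * lvs, lvs_mass = lvs,
         body_weight = max(stats::rnorm(1, a$bw, a$bw_sd), 10),
         hematocrit = hct,
         ohp = ohp_true, pyd = max(stats::rnorm(1, a$pyd, a$pyd_sd), 0.005),
         aortic_pressure = stats::rnorm(1, a$aop, a$aop_sd)),
       cd_true = cd, ohp_true = ohp_true)
}

#' Generate a synthetic four-group cohort with known ground truth
#'
#' For each animal: draws generator parameters and covariates from its
#' group spec ([default_group_specs]), then simulates one continuous
#' recording containing a steady baseline followed by a vena-cava-occlusion
#' maneuver and recovery ([simulate_vco]). OHP/PYD assay values are masked
#' to `NA` outside the per-group assay subset, as destructive assays only
#' cover some animals; the unmasked values remain in the truth manifest.
#'
#' @param specs list of `group_spec`s (default [default_group_specs]).
#' @param seed integer master seed; all draws and simulation noise derive
#'   from it, so identical seeds give bit-identical cohorts.
#' @param pre_beats,ramp_beats,hold_beats,post_beats,ramp_depth,refill_tau
#'   occlusion-recording layout, passed to [simulate_vco].
#' @param waveforms if `FALSE`, only parameters and covariates are drawn
#'   (same RNG stream as a full run) and no recordings are simulated.
#' @return list of class `pv_cohort`: `waveforms` (named list of
#'   [pv_waveform]s), `animals` (animal table), `truth` (per-animal
#'   data.frame of true generator parameters).
#' @export
generate_cohort <- function(specs = default_group_specs(), seed = 1,
                            pre_beats = 14, ramp_beats = 10, hold_beats = 2,
                            post_beats = 12, ramp_depth = 0.6,
                            refill_tau = 0.25, waveforms = TRUE) {
  draws <- with_seed(seed, {
    out <- list()
    idx <- 0L
    for (spec in specs) {
      for (i in seq_len(spec$n_animals)) {
        idx <- idx + 1L
        sid <- sprintf("%s_%02d", spec$group_label, i)
        sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        out[[idx]] <- c(draw_animal(spec, sid, sim_seed),
                        list(spec = spec, ord = i))
      }
    }
    out
  })
  wf <- list()
  animals <- list()
  truth <- list()
  for (d in draws) {
    if (waveforms)
      wf[[d$animal$subject_id]] <- simulate_vco(
        d$params, ramp_beats = ramp_beats, ramp_depth = ramp_depth,
        pre_beats = pre_beats, hold_beats = hold_beats,
        post_beats = post_beats, refill_tau = refill_tau,
        subject_id = d$animal$subject_id,
        group_label = d$animal$group_label)
    animals[[length(animals) + 1L]] <- d$animal
    truth[[length(truth) + 1L]] <- data.frame(
      subject_id = d$animal$subject_id, group_label = d$animal$group_label,
      emax = d$params$emax, emin = d$params$emin, v0 = d$params$v0,
      hr = d$params$hr, rp = d$params$afterload$rp,
      c_art = d$params$afterload$c, p_ven = d$params$preload$p_ven,
      cd_true = d$cd_true, ohp_true = d$ohp_true,
      sim_seed = d$params$seed)
  }
  animals <- do.call(rbind, animals)
  # mask assay values outside the per-group assay subsets
  for (spec in specs) {
    rows <- which(animals$group_label == spec$group_label)
    if (length(rows) > spec$animal$ohp_n)
      animals$ohp[rows[(spec$animal$ohp_n + 1L):length(rows)]] <- NA_real_
    if (length(rows) > spec$animal$pyd_n)
      animals$pyd[rows[(spec$animal$pyd_n + 1L):length(rows)]] <- NA_real_
  }
  structure(list(waveforms = wf, animals = validate_animal_table(animals),
                 truth = do.call(rbind, truth), seed = seed),
            class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat(sprintf("pv_cohort: %d animals in %d groups (seed %s)\n",
              nrow(x$animals), length(unique(x$animals$group_label)),
              format(x$seed)))
  print(table(x$animals$group_label))
  invisible(x)
}
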