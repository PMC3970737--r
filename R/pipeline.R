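#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with its documented default, so a
#' run is fully described by (config, inputs, seed). The config is
#' serialized as YAML into the output directory by the `cmd_*` stages, and
#' the report logs the definitional choices in effect (pulse-pressure
#' definition, tau method), making reported indices self-describing.
#'
#' @param outdir output directory for stage products.
#' @param seed master seed used by simulation and Monte-Carlo statistics.
#' @param steady_n minimum consecutive clean beats for the steady window.
#' @param min_rr_ms,window_ms beat segmentation tunables ([segment_beats]).
#' @param rr_tolerance extrasystole RR tolerance ([flag_extrasystoles]).
#' @param drop_fraction,min_occl_beats occlusion detection tunables
#'   ([detect_occlusion]).
#' @param tau_method `"weiss"` or `"glantz"` ([fit_tau]).
#' @param pp_def pulse-pressure definition ([beat_indices]).
#' @param n_perm permutations for Spearman tests.
#' @param mc_reps Monte-Carlo draws for Dunnett comparisons.
#' @param control_group control group label for many-to-one comparisons.
#' @param specs group specs for simulation (default [default_group_specs]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("pvrun"), seed = 1,
                            steady_n = 10, min_rr_ms = 60, window_ms = 5,
                            rr_tolerance = 0.15, drop_fraction = 0.10,
                            min_occl_beats = 4, tau_method = "weiss",
                            pp_def = "min_diastolic", n_perm = 10000,
                            mc_reps = 4000, control_group = "normoxia",
                            specs = default_group_specs()) {
  structure(list(outdir = outdir, seed = seed, steady_n = steady_n,
                 min_rr_ms = min_rr_ms, window_ms = window_ms,
                 rr_tolerance = rr_tolerance, drop_fraction = drop_fraction,
                 min_occl_beats = min_occl_beats, tau_method = tau_method,
                 pp_def = pp_def, n_perm = n_perm, mc_reps = mc_reps,
                 control_group = control_group, specs = specs),
            class = "pipeline_config")
}

serialize_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$specs <- lapply(cfg$specs, unclass)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Analyze one pressure-volume recording end to end
#'
#' Runs the full single-animal pipeline: beat segmentation, extrasystole
#' flagging, occlusion detection, steady-window index extraction,
#' per-occlusion-run ESPVR / PRSW / EDPVR fits and recovery count, and
#' aggregation into one hemodynamic record. Ees and PRSW are the means over
#' all detected occlusion runs (runs are fit independently); if no
#' occlusion is present the load-independent indices are `NA` and the rest
#' of the record is still populated.
#'
#' @param w a [pv_waveform].
#' @param animal optional one-row animal-table entry.
#' @param config a [pipeline_config].
#' @return list of class `pv_analysis`: `record` (one-row
#'   [aggregate_record] frame), `beats`, `runs` (per-run fit summaries),
#'   `steady_beats` row count.
#' @export
analyze_waveform <- function(w, animal = NULL, config = pipeline_config()) {
  beats <- segment_beats(w, min_rr_ms = config$min_rr_ms,
                         window_ms = config$window_ms)
  beats <- flag_extrasystoles(beats, rr_tolerance = config$rr_tolerance)
  occ <- detect_occlusion(w, beats, drop_fraction = config$drop_fraction,
                          min_beats = config$min_occl_beats)
  beats <- occ$beats
  steady <- select_steady_window(beats, n = config$steady_n)
  idx <- do.call(rbind, lapply(seq_len(nrow(steady)), function(k)
    beat_indices(w, steady[k, ], tau_method = config$tau_method,
                 pp_def = config$pp_def)))
  run_fits <- lapply(occ$runs, function(run) {
    fit_rows <- run$beat_rows[-1L]
    ridx <- do.call(rbind, lapply(fit_rows, function(k)
      beat_indices(w, beats[k, ], tau_method = config$tau_method,
                   pp_def = config$pp_def)))
    es <- tryCatch(fit_espvr(w, run, beats), error = function(e) NULL)
    pr <- tryCatch(fit_prsw(ridx), error = function(e) NULL)
    ed <- tryCatch(fit_edpvr(ridx), error = function(e) NULL)
    rec_n <- tryCatch(recovery_beats(w, run, beats), error = function(e) NA_integer_)
    list(espvr = es, prsw = pr, edpvr = ed, recovery_beats = rec_n)
  })
  ees_runs <- vapply(run_fits, function(f)
    if (!is.null(f$espvr)) f$espvr$ees else NA_real_, numeric(1L))
  prsw_runs <- vapply(run_fits, function(f)
    if (!is.null(f$prsw)) f$prsw$prsw else NA_real_, numeric(1L))
  ees <- if (any(is.finite(ees_runs))) mean(ees_runs, na.rm = TRUE) else NA_real_
  prsw <- if (any(is.finite(prsw_runs))) mean(prsw_runs, na.rm = TRUE) else NA_real_
  rec <- aggregate_record(idx, animal = animal, ees = ees, prsw = prsw)
  if (length(run_fits)) {
    rb <- vapply(run_fits, function(f) as.numeric(f$recovery_beats %||% NA), numeric(1L))
    rec$recovery_beats <- if (any(is.finite(rb))) mean(rb, na.rm = TRUE) else NA_real_
    v0s <- vapply(run_fits, function(f)
      if (!is.null(f$espvr)) f$espvr$v0 else NA_real_, numeric(1L))
    rec$v0 <- if (any(is.finite(v0s))) mean(v0s, na.rm = TRUE) else NA_real_
    eds <- vapply(run_fits, function(f)
      if (!is.null(f$edpvr)) f$edpvr$slope else NA_real_, numeric(1L))
    rec$edpvr_slope <- if (any(is.finite(eds))) mean(eds, na.rm = TRUE) else NA_real_
  } else {
    rec$recovery_beats <- NA_real_
    rec$v0 <- NA_real_
    rec$edpvr_slope <- NA_real_
  }
  structure(list(record = rec, beats = beats, runs = run_fits,
                 steady_beats = nrow(steady)),
            class = "pv_analysis")
}

#' Analyze every animal of a cohort
#'
#' Applies [analyze_waveform] per animal; a failing recording is reported
#' as a named warning and skipped, so one corrupt file does not abort the
#' cohort.
#'
#' @param cohort a `pv_cohort` from [generate_cohort], or a list with
#'   `waveforms` and `animals`.
#' @param config a [pipeline_config].
#' @return data.frame of per-animal hemodynamic records.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config()) {
  recs <- list()
  for (sid in names(cohort$waveforms)) {
    arow <- cohort$animals[cohort$animals$subject_id == sid, , drop = FALSE]
    if (!nrow(arow)) arow <- NULL
    res <- tryCatch(analyze_waveform(cohort$waveforms[[sid]], arow, config),
                    error = function(e) {
                      warnf("analysis failed for %s: %s", sid, conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) recs[[length(recs) + 1L]] <- res$record
  }
  if (!length(recs)) stopf("no recording could be analyzed")
  do.call(rbind, recs)
}

#' Simulation stage: write a synthetic cohort to disk
#'
#' Generates the configured cohort and writes one waveform CSV per animal,
#' the animal table, the ground-truth manifest, and the serialized config
#' into `config$outdir`.
#'
#' @param config a [pipeline_config].
#' @return the output directory, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$specs, seed = config$seed)
  for (sid in names(cohort$waveforms))
    write_pv_waveform(cohort$waveforms[[sid]],
                      file.path(config$outdir, paste0(sid, ".csv")))
  write_animal_table(cohort$animals, file.path(config$outdir, "animals.csv"))
  utils::write.csv(cohort$truth, file.path(config$outdir, "truth.csv"),
                   row.names = FALSE)
  serialize_config(config, file.path(config$outdir, "config.yaml"))
  invisible(config$outdir)
}

#' Analysis stage: per-animal records from waveform files
#'
#' Reads every waveform CSV in `input_dir` (all `*.csv` except the table
#' files), joins the animal table if present, analyzes each recording and
#' writes `records.csv` into `config$outdir`. Per-file failures are
#' reported by name and skipped.
#'
#' @param config a [pipeline_config].
#' @param input_dir directory of waveform CSVs (default `config$outdir`).
#' @return the records data.frame, invisibly.
#' @export
cmd_analyze <- function(config = pipeline_config(), input_dir = config$outdir) {
  files <- setdiff(list.files(input_dir, pattern = "\\.csv$", full.names = TRUE),
                   file.path(input_dir, c("animals.csv", "truth.csv", "records.csv",
                                          "cohort_summary.csv", "dunnett.csv",
                                          "report_table.csv")))
  if (!length(files)) stopf("no waveform CSVs found in %s", input_dir)
  animals_path <- file.path(input_dir, "animals.csv")
  animals <- if (file.exists(animals_path)) read_animal_table(animals_path) else NULL
  waveforms <- list()
  for (f in files) {
    w <- tryCatch(read_pv_waveform(f), error = function(e) {
      warnf("skipping %s: %s", basename(f), conditionMessage(e))
      NULL
    })
    if (!is.null(w)) waveforms[[w$subject_id]] <- w
  }
  cohort <- list(waveforms = waveforms,
                 animals = animals %||% data.frame(subject_id = character(0),
                                                   group_label = character(0)))
  records <- analyze_cohort(cohort, config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(config$outdir, "records.csv"),
                   row.names = FALSE)
  serialize_config(config, file.path(config$outdir, "config.yaml"))
  invisible(records)
}

#' Report stage: cohort summary, group comparisons, fibrosis correlation
#'
#' From per-animal records, produces the group-level summary (mean, SE,
#' per-field n), Dunnett comparisons of every field against the control
#' group (skipped with a notice when only one group is present), the
#' group-mean collagen-compliance correlation, and a publication-style
#' table (`mean +/- SE` cells with a significance marker vs control at
#' p < 0.05). All outputs are written as CSVs into `config$outdir`.
#'
#' @param config a [pipeline_config].
#' @param records records data.frame (default: `records.csv` in outdir).
#' @param fields fields to compare across groups.
#' @return list with `cohort`, `dunnett`, `correlation`, invisibly.
#' @export
cmd_report <- function(config = pipeline_config(),
                       records = utils::read.csv(file.path(config$outdir, "records.csv")),
                       fields = c("rvsp", "rvedp", "lvs_mass", "body_weight",
                                  "fulton", "hematocrit", "compliance", "tau",
                                  "edv", "esv", "sv", "hr", "ef", "co", "sw",
                                  "sw_density", "tpvr", "ea", "ees", "prsw",
                                  "eta", "dpdt_max", "dpdt_min", "ohp", "pyd",
                                  "pyd_ohp_ratio")) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fields <- intersect(fields, names(records))
  cohort <- summarize_cohort(records, fields)
  groups <- unique(records$group_label)
  dunnett <- NULL
  if (length(groups) >= 2L && config$control_group %in% groups) {
    rows <- list()
    for (f in fields) {
      vals <- split(records[[f]], records$group_label)
      vals <- lapply(vals, function(x) x[is.finite(x)])
      vals <- vals[lengths(vals) >= 2L]
      if (length(vals) < 2L || !config$control_group %in% names(vals)) next
      res <- tryCatch(anova_dunnett(vals, control = config$control_group,
                                    mc_reps = config$mc_reps,
                                    seed = config$seed),
                      error = function(e) NULL)
      if (is.null(res)) next
      cmp <- res$comparisons
      cmp$field <- f
      cmp$anova_f <- res$statistic
      cmp$anova_p <- res$p_value
      rows[[length(rows) + 1L]] <- cmp
    }
    dunnett <- do.call(rbind, rows)
    utils::write.csv(dunnett, file.path(config$outdir, "dunnett.csv"),
                     row.names = FALSE)
  } else {
    message("single group present: group comparisons skipped")
  }
  correlation <- tryCatch(
    group_mean_correlation(cohort, "ohp", "compliance"),
    error = function(e) NULL)
  # publication-style table: variables x groups, mean +/- SE, '*' vs control
  tab <- NULL
  for (f in fields) {
    cf <- cohort[cohort$field == f, ]
    row <- stats::setNames(as.list(sprintf("%.3g ± %.2g", cf$mean, cf$se)),
                           cf$group_label)
    if (!is.null(dunnett)) {
      sig <- dunnett[dunnett$field == f & dunnett$p_adjusted < 0.05, "group"]
      for (gl in sig) row[[gl]] <- paste0(row[[gl]], " *")
    }
    tab <- rbind(tab, data.frame(variable = f, row, check.names = FALSE))
  }
  utils::write.csv(cohort, file.path(config$outdir, "cohort_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(tab, file.path(config$outdir, "report_table.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("pp_def: %s", config$pp_def),
               sprintf("tau_method: %s", config$tau_method),
               sprintf("control_group: %s", config$control_group),
               sprintf("seed: %s", format(config$seed)),
               if (!is.null(correlation))
                 sprintf("group-mean OHP~compliance: r2 = %.3f (slope %.3g)",
                         correlation$r2, correlation$slope)),
             file.path(config$outdir, "report_log.txt"))
  invisible(list(cohort = cohort, dunnett = dunnett, correlation = correlation))
}

#' Run simulate, analyze and report in sequence
#'
#' End-to-end deterministic pipeline under a fixed seed and config: the
#' simulated waveforms, per-animal records, cohort summary and statistics
#' land in `config$outdir`.
#'
#' @param config a [pipeline_config].
#' @return the [cmd_report] result, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cmd_simulate(config)
  records <- cmd_analyze(config)
  invisible(cmd_report(config, records))
}
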