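Package: pvloops
Title: Right-Ventricular Pressure-Volume Loop Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of murine right-ventricular (RV) pressure-volume (PV)
    catheter recordings: cardiac-cycle segmentation with extrasystole
    exclusion, steady-state hemodynamic indices (RVSP, stroke volume, stroke
    work, ejection fraction, cardiac output, total pulmonary vascular
    resistance, chamber compliance, effective arterial elastance, relaxation
    time constant tau), load-independent contractility from vena-cava
    occlusion maneuvers (iterative end-systolic pressure-volume relation
    fitting for Ees and V0, preload-recruitable stroke work, end-diastolic
    relations), ventricular-vascular coupling efficiency Ees/Ea, and cohort
    statistics (one-way ANOVA with Monte-Carlo Dunnett comparisons against a
    control group, Spearman rank correlation with permutation p-values).
    Includes a time-varying elastance plus Windkessel afterload simulator and
    a four-group cohort generator calibrated to a murine pulmonary arterial
    hypertension progression study, so that every stage of the pipeline can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
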