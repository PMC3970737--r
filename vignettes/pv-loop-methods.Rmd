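---
title: "Right-ventricular PV-loop analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Right-ventricular PV-loop analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvloops)
```

## Scope

`pvloops` analyzes synchronized right-ventricular (RV) pressure/volume
catheter recordings from mice — the kind of data used to characterize RV
adaptation in pulmonary arterial hypertension (PAH) — and ships a
mechanistic waveform simulator so that every analysis stage can be
validated against known ground truth without animal data. The pipeline
covers cardiac-cycle segmentation, steady-state hemodynamic indices,
load-independent contractility from vena-cava occlusion (VCO) maneuvers,
ventricular-vascular coupling, and cohort-level statistics.

This vignette records the scientific model behind each stage, the tunable
parameters with their defaults and units, and the design decisions taken
where the problem is genuinely underdetermined.

## The generative model

The simulator is a time-varying elastance ventricle coupled to a lumped
afterload. Instantaneous ventricular pressure is

$$P(t) = E(t)\,\bigl(V(t) - V_0\bigr), \qquad
  E(t) = E_{min} + (E_{max} - E_{min})\, e_n(t/T),$$

where $V_0$ is the unstressed volume, $E_{max}$ the end-systolic
elastance (the ground truth for Ees), $E_{min}$ the diastolic elastance
(reciprocal diastolic compliance), and $e_n \in [0,1]$ a double-Hill
activation: a rising Hill term (exponent `n1`, default 1.9) multiplied by
a falling one (exponent `n2`, default 10). Given the peak-time fraction
`t_peak` (default 0.32 of the cycle), the falling half-time is solved in
closed form from the stationarity condition so the activation peaks
exactly at `t_peak` with value exactly 1.

Filling and ejection are diode-resistive:

* filling, when $P_{ven} > P$: $\dot V = (P_{ven} - P)/R_{in}$;
* ejection, when $P > P_{art}$: $\dot V = -(P - P_{art})/R_c$, with the
  arterial (Windkessel) pressure obeying
  $\dot P_{art} = (Q_{out} - P_{art}/R_p)/C_{art}$;
* both valves closed otherwise.

The two-element proximal/distal afterload ($R_c$, $R_p$, $C_{art}$) is the
smallest model that makes effective arterial elastance (Ea), total
pulmonary vascular resistance (TPVR) and their progression trends
reproducible and monotone in $R_p$; no pulmonary tree, septal interaction
or oxygen transport is modeled. Integration is classical fourth-order
Runge-Kutta at `dt = 0.001` s (matching the 1000 Hz acquisition rate of
murine catheter systems). Sixteen initial beats are integrated and
discarded so recordings start in periodic steady state (the arterial
time constant $R_pC_{art}$ is roughly one beat; sixteen beats push the
residual transient below the 0.1% loop-to-loop reproducibility the tests
assert). Measurement noise is additive i.i.d. Gaussian on pressure
(SD 0.5 mmHg) and volume (SD 0.3 uL), applied after integration under a
caller-provided seed; baseline drift and admittance-calibration error are
not modeled, so robustness to those must not be inferred from passing
tests.

A VCO maneuver ramps $P_{ven}$ down linearly over `ramp_beats` cycles
(default 10, depth 0.6), holds two cycles, and releases it with a
first-order venous refill time constant (default 0.25 s). Because
$P = E(t)(V - V_0)$ holds identically, the occlusion sweeps the true
end-systolic points down the line $P = E_{max}(V - V_0)$, giving exact
ground truth for the ESPVR estimators.

## Beat segmentation

Beats are anchored at dP/dt-max peaks — the sharpest, most noise-robust
fiducial in RV traces — found on a Savitzky-Golay (quadratic, 5 ms)
smoothed derivative with a minimum spacing `min_rr_ms = 60` ms (a
1000 bpm ceiling). End-diastole is the pressure minimum in a 20 ms window
before each peak, searched on smoothed pressure with an
earliest-within-band tie-break: the diastolic floor is nearly flat at the
noise level, and without the band the argmin jitters the beat boundary by
up to 10 ms. Peaks too close to the recording start to contain a full ED
window are dropped rather than accepted with a truncated (biased) RR.
Beats tile the recording half-open ED-to-ED without overlap.

End-systole is operationalized as the point of maximal elastance — the
sample maximizing $P/(V - v_0)$ between dP/dt-max and dP/dt-min — rather
than the dP/dt-min instant, so the steady-state ES definition and the
ESPVR construction coincide. For steady beats $v_0 = 0$ is conventional;
during iterative ESPVR fitting the current $V_0$ estimate is used.

Extrasystoles are flagged when a beat's RR interval deviates more than
15% from a 7-beat running median, with a sticky flag on the following
beat (compensatory pause); the threshold is a documented default, not a
claim about any particular acquisition software. Steady-state indices are
computed on the earliest run of at least 10 consecutive clean,
non-occlusion beats.

## Steady-state indices

Per beat: RVSP is the pressure maximum; EDV/ESV are the volume
maximum/minimum (robust to small P-V phase offsets from catheter
positioning, rather than volumes at pressure fiducials); SV = EDV - ESV
exactly; EF = SV/EDV; stroke work is the shoelace area of the closed
(V, P) polygon. Pressure and volume are lightly smoothed (quadratic, 5 ms)
before extrema are read so noise does not inflate max/min-based indices;
the tau fit always uses raw pressure. Aggregation uses means of per-beat
ratios (e.g. mean per-beat EF), not ratios of means.

Derived, per animal: HR = 60000/mean(RR); CO = SV x HR; TPVR = RVSP/CO
(CO in mL/min); chamber compliance = SV/PP with pulse pressure
PP = RVSP minus the minimum diastolic pressure. The SV/PP definition was
chosen because it reproduces the reference cohort's printed compliance
column from its own SV and RVSP columns to within two standard errors in
all four groups; whether PP should instead be RVSP - RVEDP is not
determinable from group summaries, so both are implemented (`pp_def`) and
the choice is logged in every report. Ea = ESP/SV with ESP read at the
detected ES point (a config switch allows the common ESP := RVSP
approximation; the default keeps Ea and Ees on the same ES definition so
the coupling ratio eta = Ees/Ea is internally consistent). SW density
divides stroke work by RV free-wall tissue volume assuming density
1.053 mg/uL; the Fulton index is RV mass over LV+septum mass.

The relaxation constant tau is fit from dP/dt-min to the first sample at
or below max(next RVEDP, 10% of RVSP). The default is the zero-asymptote
(Weiss) log-linear fit, matching the single-constant relaxation factor
convention; the Glantz variable-asymptote exponential is available and is
the automatic fallback when the window contains non-positive pressures.

## VCO fitting

Occlusion transients are detected on the per-beat RVSP series (3-beat
running mean): maximal spans that fall essentially monotonically (per-beat
rises up to 2% of baseline tolerated) by at least 10% of the
pre-occlusion baseline, with at least 4 beats. The run's leading plateau
is trimmed to where RVSP actually leaves baseline (within 3%), and the
run ends at the raw-RVSP nadir — the smoothed series turns up one beat
early because its 3-beat window already contains the first recovery beat.

The ESPVR is fit by the standard iterative scheme: with the current
$v_0$, each beat's ES point is the argmax of $P/(V - v_0)$; a
least-squares line through the (V\_es, P\_es) points updates $v_0$ to its
volume intercept; iteration starts at $v_0 = 0$ (safely below murine
ESV) and stops when $v_0$ moves less than 0.01 uL. The first beat after
occlusion onset is dropped as a transient. ES coordinates are read from
9 ms-smoothed signals: reading raw samples at the selected instant both
dilutes the slope (volume noise) and couples to the argmax selection,
which at low volumes systematically picks noise-up pressure and
noise-down volume and flattened the fitted slope by ~10-25% before this
choice. A linear (not parabolic) ESPVR is fit because a single slope Ees
is the reported contractility index; multiple runs per recording are fit
independently and averaged. PRSW is the least-squares slope of stroke
work on EDV (units mmHg); the linear EDPVR slope approximates reciprocal
diastolic compliance, with a known flattening (~10-15%) because the
dynamic EDP fiducial is read before filling fully completes. Recovery is
quantified as the number of post-nadir beats until RVSP first regains
95% of baseline.

With these choices, across 100 simulated occlusions with Emax in
[1, 5] mmHg/uL and V0 in [0, 6] uL at the default noise, the tests
require (and the acceptance script recomputes) a median relative Emax
error below 5% and a median V0 error below 1 uL; noise-free recovery is
exact to well under 2% and 0.5 uL.

## Cohort statistics

Group summaries report per-field n (assay values missing for an animal
are excluded field-wise), mean, and SE = SD/sqrt(n) (zero, flagged, for
n = 1). Group comparisons use one-way ANOVA with Dunnett many-to-one
contrasts against the control group; adjusted two-sided p-values come
from the null distribution of the maximum |t|, sampled by seeded Monte
Carlo from the fitted null (4000 draws by default). Monte Carlo rather
than table lookup keeps the procedure exact in distribution at arbitrary
unbalanced group sizes (the reference cohort has n = 8-9); the unit tests
cross-check the adjusted p-values against `multcomp`'s multivariate-t
integration and calibrate the family-wise error to 0.05 over 2000 null
replicates. Spearman rank correlation uses midranks (the reference
compliance column contains a group-level tie) with a two-sided
permutation p-value using the add-one estimator
$(1 + \#\{|r_{perm}| \ge |r_s|\})/(n_{perm}+1)$, which is valid at any
permutation count. Simple linear correlation is ordinary least squares;
the group-mean fibrosis-compliance correlation applies it to the four
group means. All tests are two-sided.

On the packaged reference table, the four group-mean collagen (OHP)
values against the four group-mean compliance values give R^2 = 0.98;
the midrank Spearman coefficient on those group means is -0.95. A
rank correlation computed on individual animals (not available in group
summaries) would generally differ from the group-mean value.

## The cohort generator and its calibration

`default_group_specs()` encodes four groups (normoxia and 14-, 21-,
28-day hypoxia+SU5416 exposure; n = 8/9/9/8). Covariates (LV+septum
mass, body weight, hematocrit, Fulton index, OHP, PYD, aortic pressure)
are drawn from group normal distributions with SD = SE x sqrt(n) so the
emitted cohort reproduces the reference mean +/- SE structure; RV mass is
drawn via the Fulton index times the drawn LV+septum mass. OHP and PYD
are reported for 5 and 4 animals per group respectively (destructive
assays cover a subset), but every animal's latent OHP drives its
diastolic stiffness: diastolic compliance is
`28.5 - 1.53 x OHP + N(0, 1)` uL/mmHg and $E_{min}$ its reciprocal.
The linkage line was obtained by regressing, across the four groups, the
diastolic compliance implied by the reference EDP and EDV values
(`(EDV - V0)/EDP`) on the reference OHP means; it makes collagen content
and analyzed chamber compliance negatively correlated across the cohort
by mechanism, not by construction of the measured index.

The hemodynamic parameters are set as follows. Heart rate comes from the
reference group means (SD = SE x sqrt(n)). Contractility `emax` is
2.6/4.0/4.1/4.2 mmHg/uL — an early rise with a later plateau, the
characteristic adaptive-contractility pattern, at murine magnitudes.
Distal resistance rises monotonically (0.085/0.133/0.173/0.218
mmHg s/uL) and arterial compliance falls (0.80/0.60/0.50/0.45 uL/mmHg)
with exposure severity, encoding progressive distal arterial occlusion
and stiffening. Given those, venous pressure and distal resistance were
jointly calibrated, group by group, so that the *analyzed* group means of
RVSP and SV (through the full segmentation-and-index pipeline, at default
noise) land on the reference values 26/37/41/45 mmHg and
14.7/14.9/14.2/13.4 uL; per-animal log-normal jitter (CV 4-5%) on emax,
rp and p_ven provides biological spread. Calibrating through the
analyzer, rather than to simulator truth, is deliberate: the published
values are themselves products of an analysis pipeline applied to noisy
signals.

The preset file `inst/extdata/presets.yaml` mirrors these numbers with
their provenance; `reference_cohort()` exposes the target table.

What the generator does *not* emulate: baseline drift, respiratory
modulation, catheter repositioning artifacts, ECG gating, inter-beat
contractility variation, and any tissue-level mechanism linking exposure
to afterload. Passing tests therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to every artifact
of real recordings.

## Numerical choices and degenerate inputs

* Validation is strict and non-repairing: non-monotone time, non-finite
  samples, non-positive volumes, out-of-range hematocrit and duplicated
  subject IDs are errors naming the offending entry.
* Ties in the ES argmax break to the earliest sample; the ED minimum uses
  an earliest-within-band (10% of window range) tie-break.
* `fit_espvr` clamps the $v_0$ iterate 0.5 uL below the run's minimum
  volume so the elastance ratio stays defined, reports non-convergence
  rather than failing, and raises a diagnostic error if the slope turns
  non-positive (non-physiological ESPVR).
* Flat or too-short fit windows (tau, PRSW, EDPVR with < 4-5 points,
  zero EDV variance) are errors; a failed tau fit inside the per-beat
  index extraction degrades to `NA` with a warning instead of failing the
  record.
* A recording with no occlusion yields the steady-state panel with Ees,
  PRSW and eta absent, never zero.
* Problem sizes in the tests (simulated beats per check, 10-seed cohort
  replication, 2000 null replicates for the family-wise error, 500 for
  permutation uniformity) were chosen to keep Monte-Carlo error at least
  a factor of two below each asserted tolerance.

## Known limitations

* Single-beat Ees estimation is not implemented; Ees requires a VCO run.
* The EDPVR is linear by construction; a stiffening (exponential) EDPVR
  would be the natural extension if diastolic curvature matters.
* Chamber compliance as SV/PP mixes systolic and diastolic information;
  it is reported because it matches the reference convention, with the
  diastolic filling-slope alternative available.
* Volume calibration (admittance-to-volume conversion) is assumed done
  upstream; the package consumes calibrated uL.
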