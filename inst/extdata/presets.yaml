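# Four-group murine PAH-progression simulation presets (on-disk mirror of
# default_group_specs()). Covariate means/SDs encode the reference cohort's
# group mean +/- SE structure with SD = SE * sqrt(n) (see
# extdata/reference_cohort.csv); hemodynamic parameters (emax, rp, c, p_ven)
# are calibrated so the analyzed group means of RVSP (26/37/41/45 mmHg),
# SV (14.7/14.9/14.2/13.4 uL) and HR (552/597/591/597 bpm) land on the
# reference values. Distal resistance rp rises monotonically with exposure
# severity; contractility emax rises early then plateaus. The linkage block
# ties each animal's diastolic compliance (uL/mmHg) to its collagen content:
# cd = intercept + slope * OHP + N(0, noise_sd), emin = 1/cd.
# Units: elastances mmHg/uL; resistances mmHg s/uL; compliance uL/mmHg;
# pressures mmHg; volumes uL; hr beats/min; masses mg; ohp ug/mg; pyd nmol/mg.
normoxia:
  group_label: normoxia
  n_animals: 8
  hemo: {emax: 2.6, emax_cv: 0.04, rp: 0.085, rp_cv: 0.05, p_ven: 4.83,
         p_ven_cv: 0.04, rc: 0.02, c: 0.80, r_in: 0.015, hr: 552.0,
         hr_sd: 45.0, v0: 3.0, t_peak: 0.32, n1: 1.9, n2: 10.0,
         sd_p: 0.5, sd_v: 0.3}
  animal: {lvs: 78.3, lvs_sd: 6.2, fulton: 0.26, fulton_sd: 0.028,
           bw: 25.3, bw_sd: 1.7, hct: 46.0, hct_sd: 3.1,
           ohp: 2.2, ohp_sd: 0.45, ohp_n: 5,
           pyd: 0.20, pyd_sd: 0.10, pyd_n: 4, aop: 53.0, aop_sd: 14.0}
  linkage: {intercept: 28.5, slope: -1.53, noise_sd: 1.0}
hysu14:
  group_label: hysu14
  n_animals: 9
  hemo: {emax: 4.0, emax_cv: 0.04, rp: 0.133, rp_cv: 0.05, p_ven: 5.59,
         p_ven_cv: 0.04, rc: 0.02, c: 0.60, r_in: 0.015, hr: 597.0,
         hr_sd: 51.0, v0: 3.0, t_peak: 0.32, n1: 1.9, n2: 10.0,
         sd_p: 0.5, sd_v: 0.3}
  animal: {lvs: 77.8, lvs_sd: 12.9, fulton: 0.40, fulton_sd: 0.06,
           bw: 23.2, bw_sd: 1.2, hct: 75.0, hct_sd: 6.6,
           ohp: 5.4, ohp_sd: 0.67, ohp_n: 5,
           pyd: 0.10, pyd_sd: 0.04, pyd_n: 4, aop: 55.0, aop_sd: 9.0}
  linkage: {intercept: 28.5, slope: -1.53, noise_sd: 1.0}
hysu21:
  group_label: hysu21
  n_animals: 9
  hemo: {emax: 4.1, emax_cv: 0.04, rp: 0.173, rp_cv: 0.05, p_ven: 5.48,
         p_ven_cv: 0.04, rc: 0.02, c: 0.50, r_in: 0.015, hr: 591.0,
         hr_sd: 57.0, v0: 3.0, t_peak: 0.32, n1: 1.9, n2: 10.0,
         sd_p: 0.5, sd_v: 0.3}
  animal: {lvs: 79.5, lvs_sd: 7.8, fulton: 0.43, fulton_sd: 0.03,
           bw: 23.2, bw_sd: 2.7, hct: 74.0, hct_sd: 3.6,
           ohp: 5.3, ohp_sd: 1.34, ohp_n: 5,
           pyd: 0.08, pyd_sd: 0.02, pyd_n: 4, aop: 59.0, aop_sd: 3.0}
  linkage: {intercept: 28.5, slope: -1.53, noise_sd: 1.0}
hysu28:
  group_label: hysu28
  n_animals: 8
  hemo: {emax: 4.2, emax_cv: 0.04, rp: 0.218, rp_cv: 0.05, p_ven: 5.49,
         p_ven_cv: 0.04, rc: 0.02, c: 0.45, r_in: 0.015, hr: 597.0,
         hr_sd: 48.0, v0: 3.0, t_peak: 0.32, n1: 1.9, n2: 10.0,
         sd_p: 0.5, sd_v: 0.3}
  animal: {lvs: 78.9, lvs_sd: 12.7, fulton: 0.44, fulton_sd: 0.085,
           bw: 24.1, bw_sd: 1.7, hct: 61.0, hct_sd: 1.1,
           ohp: 7.1, ohp_sd: 1.12, ohp_n: 5,
           pyd: 0.16, pyd_sd: 0.08, pyd_n: 4, aop: 55.0, aop_sd: 3.0}
  linkage: {intercept: 28.5, slope: -1.53, noise_sd: 1.0}
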