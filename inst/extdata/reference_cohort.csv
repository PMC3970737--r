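# Published group means +/- SE of the murine PAH progression cohort that the
# shipped simulation presets are calibrated to reproduce (hemodynamics and
# morphometry; collagen biochemistry). Units: rvsp/rvedp/aop mmHg; lvs_mass mg;
# body_weight g; fulton mg/mg; hematocrit %; compliance uL/mmHg; tau ms;
# edv/esv/sv uL; hr beats/min; ohp ug/mg; pyd nmol/mg; pyd_ohp_ratio nmol/ug.
# n_assay: animals with that measurement (destructive assays cover a subset).
field,group_label,mean,se,n_assay
rvsp,normoxia,26,1,8
rvsp,hysu14,37,2,9
rvsp,hysu21,41,2,9
rvsp,hysu28,45,1,8
rvedp,normoxia,0.8,0.1,8
rvedp,hysu14,1.2,0.1,9
rvedp,hysu21,1.4,0.1,9
rvedp,hysu28,1.4,0.2,8
lvs_mass,normoxia,78.3,2.2,8
lvs_mass,hysu14,77.8,4.3,9
lvs_mass,hysu21,79.5,2.6,9
lvs_mass,hysu28,78.9,4.5,8
body_weight,normoxia,25.3,0.6,8
body_weight,hysu14,23.2,0.4,9
body_weight,hysu21,23.2,0.9,9
body_weight,hysu28,24.1,0.6,8
fulton,normoxia,0.26,0.01,8
fulton,hysu14,0.40,0.02,9
fulton,hysu21,0.43,0.01,9
fulton,hysu28,0.44,0.03,8
hematocrit,normoxia,46,1.1,8
hematocrit,hysu14,75,2.2,9
hematocrit,hysu21,74,1.2,9
hematocrit,hysu28,61,0.4,8
compliance,normoxia,0.53,0.03,8
compliance,hysu14,0.36,0.04,9
compliance,hysu21,0.36,0.03,9
compliance,hysu28,0.30,0.01,8
tau,normoxia,5.7,0.5,8
tau,hysu14,3.1,0.6,9
tau,hysu21,4.9,0.4,9
tau,hysu28,5.0,0.3,8
edv,normoxia,23.8,1.0,8
edv,hysu14,26.4,3.1,9
edv,hysu21,28.9,2.2,9
edv,hysu28,29.9,1.5,8
esv,normoxia,9.8,0.6,8
esv,hysu14,12.4,2.6,9
esv,hysu21,14.8,1.9,9
esv,hysu28,16.5,1.3,8
sv,normoxia,14.7,1.0,8
sv,hysu14,14.9,1.4,9
sv,hysu21,14.2,1.0,9
sv,hysu28,13.4,0.7,8
hr,normoxia,552,16,8
hr,hysu14,597,17,9
hr,hysu21,591,19,9
hr,hysu28,597,17,8
aortic_pressure,normoxia,53,5,8
aortic_pressure,hysu14,55,3,9
aortic_pressure,hysu21,59,1,9
aortic_pressure,hysu28,55,1,8
ohp,normoxia,2.2,0.2,5
ohp,hysu14,5.4,0.3,5
ohp,hysu21,5.3,0.6,5
ohp,hysu28,7.1,0.5,5
pyd,normoxia,0.20,0.05,4
pyd,hysu14,0.10,0.02,4
pyd,hysu21,0.08,0.01,4
pyd,hysu28,0.16,0.04,4
pyd_ohp_ratio,normoxia,0.10,0.03,4
pyd_ohp_ratio,hysu14,0.02,0.005,4
pyd_ohp_ratio,hysu21,0.02,0.005,4
pyd_ohp_ratio,hysu28,0.02,0.01,4
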