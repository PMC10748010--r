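# Paclitaxel: 3-h IV infusion of 175 mg/m2 (single dose, linearized at this
# dose level). Binding essentially albumin-only; cleared by CYP3A4 and CYP2C8
# in similar proportion with minor biliary and renal routes. Clearance is
# anchored to the non-pregnant cancer exposure (AUC 17.5 mg*h/L at 325.5 mg);
# v1 calibrated to the 3.8 mg/L peak with calibrate_v1(), v2/q fixed for a
# plausible biphasic tail.
name: paclitaxel
units: mg/L
binding:
  fu_ref: 0.05
  load_albumin: 19.0
  load_agp: 0.0
elimination:
  fm_cyp3a4: 0.40
  fm_cyp2c8: 0.40
  fm_other_hepatic: 0.10
  f_renal: 0.10
  reference_population: cancer
  anchor:
    dose_mg: 325.5
    auc_mg_h_l: 17.5
disposition:
  v1: 33.28
  v2: 100.0
  q_inter: 8.0
default_regimen:
  route: iv_infusion
  dose_mg_per_m2: 175.0
  infusion_duration: 3.0
  n_doses: 1
sim:
  dt: 0.05
  t_end: 72.0
schedule: [0.5, 1.0, 2.0, 3.0, 3.25, 4.0, 6.0, 8.0, 12.0, 24.0]
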