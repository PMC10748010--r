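# Docetaxel: 1-h IV infusion of 100 mg/m2. Binds albumin and AGP; the
# two-protein partition is solved on load from the healthy/cancer fu pair
# (0.07 -> 0.06 at albumin x0.85, AGP x2.0), with lipoprotein binding folded
# into the albumin term. CYP3A4 dominates elimination. Clearance anchored to
# the non-pregnant cancer exposure (AUC 3.5 mg*h/L at 182 mg); v1 calibrated
# to the 2.5 mg/L peak.
name: docetaxel
units: mg/L
binding:
  fu_ref: 0.07
  calibrate:
    fu_alt: 0.06
    albumin_scalar: 0.85
    agp_scalar: 2.0
elimination:
  fm_cyp3a4: 0.80
  fm_cyp2c8: 0.0
  fm_other_hepatic: 0.15
  f_renal: 0.05
  reference_population: cancer
  anchor:
    dose_mg: 182.0
    auc_mg_h_l: 3.5
disposition:
  v1: 22.42
  v2: 300.0
  q_inter: 20.0
default_regimen:
  route: iv_infusion
  dose_mg_per_m2: 100.0
  infusion_duration: 1.0
  n_doses: 1
sim:
  dt: 0.05
  t_end: 72.0
schedule: [0.5, 1.0, 2.0, 3.0, 3.25, 4.0, 6.0, 8.0, 12.0, 24.0]
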