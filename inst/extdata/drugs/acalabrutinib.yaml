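# Acalabrutinib: 100 mg orally twice daily, evaluated at steady state on
# day 8 (16 doses). Highly bound (fu 0.03) with the albumin/AGP split solved
# so that cancer physiology leaves fu unchanged (predicted healthy/cancer
# exposure ratio ~1). CYP3A4 ~80% of clearance, the rest glutathione
# conjugation and amide hydrolysis (other hepatic, not enzyme-scaled).
# Clearance anchored to the predicted cancer steady-state AUC_0-24h of
# 1719 ng*h/mL (two 12-h intervals) with Fabs*Fg fixed at 0.25; rapid
# absorption (ka 2/h); v1 calibrated to the 566 ng/mL steady-state peak.
name: acalabrutinib
units: ng/mL
fabs_fg: 0.25
binding:
  fu_ref: 0.03
  calibrate:
    fu_alt: 0.03
    albumin_scalar: 0.85
    agp_scalar: 2.0
elimination:
  fm_cyp3a4: 0.80
  fm_cyp2c8: 0.0
  fm_other_hepatic: 0.20
  f_renal: 0.0
  reference_population: cancer
  anchor:
    dose_mg: 100.0
    auc_0_24_ng_h_ml: 1719.0
    n_intervals: 2
disposition:
  v1: 11.35
  v2: 10.0
  q_inter: 5.0
  ka: 2.0
default_regimen:
  route: oral
  dose_mg: 100.0
  tau: 12.0
  n_doses: 16
sim:
  dt: 0.05
  t_end: 192.0
schedule: [0.25, 0.5, 1.0, 2.0, 4.0, 6.0, 8.0, 12.0]
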