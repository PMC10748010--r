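---
title: "Translating oncology-drug pharmacokinetics into pregnancy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating oncology-drug pharmacokinetics into pregnancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravipk)
```

## The problem

Pregnant patients with cancer are almost absent from clinical trials, yet both
pregnancy and cancer change the physiology that determines drug exposure:
plasma binding proteins (albumin falls in both conditions; alpha-1-acid
glycoprotein, AGP, roughly doubles in cancer but falls ~30% by the third
trimester), hepatic CYP3A4 and CYP2C8 abundance (induced in pregnancy), and
glomerular filtration (reduced in cancer, increased in pregnancy). `gravipk`
implements a mechanistic translation layer that takes a drug's
pharmacokinetics observed in non-pregnant patients with cancer and predicts
exposure in pregnant patients, for three bundled drugs: paclitaxel and
docetaxel (IV taxanes used to evaluate the population models) and
acalabrutinib (an oral BTK inhibitor to which the selected model is applied).

## Population physiology

`make_population()` encodes multiplicative scalers relative to a healthy
non-pregnant reference (`reference_physiology()`): cancer (albumin x0.85, AGP
x2.0, GFR x0.65 — the midpoint of the reported 30–40% reduction), pregnancy
at a given gestational week, and a CYP2C8-modified pregnancy variant
(additionally CYP2C8 x2.5 throughout pregnancy). Pregnancy time-courses are
piecewise-linear in gestational week through three anchors: 1.0 at
conception, the 32-week population value (albumin 0.75, AGP 0.70, CYP3A4
2.0, GFR 1.25), and CYP3A4 2.3-fold at term. Between-anchor behaviour is not
reported for every parameter; linear interpolation is the least-structured
choice and is exact at the 32-week evaluation point used throughout.

The reference values themselves are only reported as ranges, so the package
fixes one representative set: albumin 45 g/L, AGP 0.8 g/L, GFR 110 mL/min,
hepatic blood flow 90 L/h, body weight 70 kg, CYP2C8 24 pmol/mg microsomal
protein, and BSA 1.86 m² — chosen so that the standard paclitaxel dose of
175 mg/m² resolves to 325.5 mg, which makes the published paclitaxel AUC/CL
pair internally consistent (dose = CL x AUC). The blood:plasma ratio is taken
as 1 for all three drugs, so plasma clearances combine directly with hepatic
blood flow; hepatic blood flow is held constant across populations (whether
the commercial pregnancy model scales it is not reported).

## Plasma binding

Binding is linear (non-saturable) to two proteins. With dimensionless bound
loads `La` and `Lg` (association constant x reference protein concentration),

    fu(salb, sagp) = 1 / (1 + La*salb + Lg*sagp),

where `salb`, `sagp` are protein levels relative to reference. The loads
satisfy `La + Lg = (1 - fu_ref)/fu_ref`. Because per-protein affinities are
not published, `solve_partition()` calibrates the split from two observed fu
values: docetaxel's healthy/cancer pair 0.07 → 0.06 gives loads
(9.48, 3.80); acalabrutinib's loads are solved so cancer physiology leaves
fu = 0.03 unchanged (consistent with its near-unity predicted healthy/cancer
exposure ratios), an 87:13 albumin:AGP split. Paclitaxel is modelled
albumin-only with fu 0.05 (reported values span 0.05–0.06; 0.05 is adopted).
Paclitaxel's concentration-dependent binding is out of scope at the single
175 mg/m² dose level, which is treated as linear.

## Clearance translation

Total clearance observed in the anchor population is split by pathway
fractions (`fm`): paclitaxel 0.40/0.40/0.10 CYP3A4/CYP2C8/other-hepatic with
0.10 renal; docetaxel 0.80/–/0.15 with 0.05 renal; acalabrutinib 0.80/–/0.20
with no renal route. `back_calculate()` inverts the well-stirred liver model
to the total intrinsic-clearance term `S = fu*CLint`:

    CLh = Qh * S / (Qh + S)   =>   S = Qh * CLh / (Qh - CLh),

and splits it across pathways proportionally to the hepatic-renormalized
`fm`. `predict_cl()` then rescales each enzyme term by the target/reference
abundance ratio and the fu ratio (other hepatic routes by fu only; biliary
and conjugative clearance is assumed population-invariant), recombines
through the well-stirred model, and scales renal clearance by the GFR and fu
ratios. Oral bioavailability uses the consistent first-pass factor
`F = Fabs*Fg * Qh / (Qh + S)` with `Fabs*Fg` fixed at 0.25 for acalabrutinib
and gut CYP3A4 not scaled by pregnancy (unreported in the source platform).

**Choice of translation reference.** The anchored clearances come from
non-pregnant patients with cancer (paclitaxel 325.5 mg / 17.5 mg·h/L =
18.6 L/h; docetaxel 182 mg / 3.5 mg·h/L = 52 L/h; acalabrutinib from the
predicted cancer steady-state AUC of 859.5 ng·h/mL per 12-h interval, giving
S = 29.1 L/h). The pregnancy scalers, however, are defined relative to the
*pre-pregnancy (healthy)* baseline. The package resolves this the way the
model-selection analysis itself does: the workflow first verifies that
healthy and cancer physiologies predict near-identical clearance for these
drugs (all ratios within 0.8–1.25, because they are moderate-extraction CYP
substrates with small renal fractions), and the cancer anchor is then used
as the baseline to which the gestational-week scalers are applied. The
anchor population itself therefore maps to the identity, and the pregnant
vs non-pregnant comparisons use the anchored values as the non-pregnant
comparator. The fully general target-versus-reference translation remains
available through `predict_cl()` and is what the workflow and
`sensitivity_analysis()` use.

## Kinetics engine and disposition calibration

Profiles come from a two-compartment model (central volume `v1`, peripheral
`v2`, inter-compartmental clearance `q`) with zero-order infusion or
first-order oral absorption, integrated with `deSolve::lsoda()` at rtol 1e-8
(tests verify agreement with hand-derived closed-form solutions to within
0.5%). Because the source models' distribution parameters are proprietary,
the shape is calibrated, not copied: `v1` is solved (`calibrate_v1()`) so the
representative-subject peak matches the published non-pregnant anchor
(paclitaxel 3.8 mg/L, docetaxel 2.5 mg/L, acalabrutinib 566 ng/mL at steady
state), with `(v2, q)` fixed once at values giving plausible terminal phases:
paclitaxel v1 33.3/v2 100/q 8 L(/h) (terminal half-life ~13 h), docetaxel
22.4/300/20 (~14 h), acalabrutinib 11.35/10/5 with ka 2.0 1/h (~1.8 h,
consistent with its rapid absorption and short half-life). Volumes are not
scaled by pregnancy — no volume changes are reported for these drugs — so
pregnancy alters peaks only through clearance and bioavailability. This is a
known limitation: the published pregnant/cancer Cmax ratio for acalabrutinib
(0.44) is lower than this reduced model can produce (~0.56, bounded below by
the AUC ratio 0.42), which we attribute to absorption/volume physiology in
the full platform that the reduced model deliberately omits.

Default grids use 0.05-h steps; IV taxanes are simulated for 72 h (about five
terminal half-lives) and acalabrutinib for 16 twice-daily doses (192 h) with
the final two intervals taken as the steady-state 24-h window after an
accumulation-convergence check (final two interval AUCs within 1%).

## Noncompartmental analysis

`compute_pk()` uses the standard linear-up/log-down trapezoid (a pure-linear
option is exposed), terminal-slope estimation by log-linear regression over
the trailing 3–6 points with the best adjusted R² (the commercial NCA tool's
selection rule is unspecified; this is the common convention),
`AUCinf = AUClast + Clast/lambda_z`, and `CL = dose/AUCinf` (IV) or apparent
`dose/AUCtau` at steady state (oral). Trial summaries report arithmetic
means, matching the "predicted mean" convention of the source tables.

## Virtual trials and synthetic data

`run_virtual_trial()` runs the 10-trials-of-10-subjects design with
log-normal (median-1) inter-individual variability — CV 30% on enzyme
abundances and 20% on binding proteins, with BSA uniform on 1.6–2.0 m².
These CVs are not published; they are tuning constants exposed in the API
and chosen as typical magnitudes for CYP abundance and protein levels in
population PBPK work. `generate_observed()` adds sparse sampling (bundled
schedules mimic the published figure time points) and a log-normal residual
error (default CV 20%). The generator reproduces what the analysis assumes —
multiplicative between-subject variability on clearance-governing physiology
and multiplicative assay noise. It does not emulate nonlinear binding,
time-varying physiology within a profile, dropout/BLQ censoring, or
covariate structure, so passing recovery tests demonstrate internal
consistency of the pipeline, not robustness to those real-data features.

`pi_coverage()` evaluates the 90% prediction interval (5th–95th percentile
band); `evaluate_prediction()` applies the two-fold and ±25% criteria.

## Model-selection workflow

`decision_workflow()` makes the published qualitative decision tree
operational with explicit thresholds: healthy-vs-cancer equivalence at
0.8–1.25 on all representative PK ratios; pregnancy-model acceptance when
AUC and CL are within ±25% of every observed pregnant dataset (the ±25%
rectangles of the published comparisons; Cmax is reported in the audit trail
but does not gate, matching the source's acceptance statements); the
two-fold range as outer bound. With the bundled fixtures the workflow
selects the default pregnancy model for docetaxel and the CYP2C8-modified
model for paclitaxel, reproducing the published conclusions.

## Numerical and design notes

- Representative-subject (variability-off) predictions are deterministic and
  are what the headline comparisons use; seeds only enter trials and
  synthetic data, always explicitly.
- `solve_partition()` refuses singular systems (equal scalers) and negative
  loads with a diagnostic rather than clipping silently.
- `steady_state_window()` errors when accumulation has not converged rather
  than returning a biased interval.
- Sparse-schedule NCA on the bundled 10-point taxane schedule carries ~3%
  trapezoidal error even noiseless; dense schedules recover clearance to
  well under 1%.
- The docetaxel dose resolves to 186 mg at the package BSA of 1.86 m²
  (published pairs imply 1.82 m²); all pregnant-vs-cancer comparisons are
  ratios and unaffected.

## Known limitations

Single liver + two-compartment disposition instead of a full organ-level
model; no fetal/placental compartments; no saturable binding or metabolism
(paclitaxel beyond 175 mg/m² is out of scope); no gut-enzyme or hepatic
blood-flow changes in pregnancy; pregnancy volume expansion not modelled
(peaks shift only via clearance); variability magnitudes assumed, not
fitted. Predictions for drugs with ADME properties unlike the three bundled
compounds (e.g. high renal fraction, transporter-dominated clearance) are
outside the validated envelope.
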