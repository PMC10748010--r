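#' Assemble a drug model
#'
#' Bundles the binding, elimination, and disposition components of a drug with
#' its default regimen and the reference physiology, ready for translation
#' across populations and simulation.
#'
#' @param name Drug name.
#' @param binding A [binding_model()].
#' @param elim An [elimination_model()].
#' @param disposition List with `v1`, `v2`, `q_inter` and, for oral drugs,
#'   `ka` (1/h).
#' @param default_regimen A [dosing_regimen()].
#' @param ref_phys A [reference_physiology()].
#' @param units Concentration units, `"mg/L"` or `"ng/mL"`.
#' @param fabs_fg Fraction absorbed times fraction escaping gut metabolism
#'   (oral drugs only).
#' @param schedule Default sparse sampling schedule, h (post first dose for IV
#'   drugs, post final dose for oral drugs at steady state).
#' @param sim List with default `dt` and `t_end` for simulation, h.
#' @return An object of class `drug_model`.
#' @export
drug_model <- function(name, binding, elim, disposition, default_regimen,
                       ref_phys = reference_physiology(), units = "mg/L",
                       fabs_fg = NULL, schedule = NULL,
                       sim = list(dt = 0.05, t_end = NULL)) {
  stopifnot(inherits(binding, "binding_model"),
            inherits(elim, "elimination_model"),
            inherits(default_regimen, "dosing_regimen"),
            inherits(ref_phys, "ref_physiology"))
  units <- match.arg(units, c("mg/L", "ng/mL"))
  if (default_regimen$route == "oral") {
    if (is.null(fabs_fg)) stop("oral drugs need fabs_fg")
    if (is.null(disposition$ka)) stop("oral drugs need an absorption rate ka")
  }
  qh <- ref_phys$hepatic_blood_flow
  intrinsic <- back_calculate(elim, qh)
  structure(list(name = name, units = units,
                 conc_scale = if (units == "ng/mL") 1000 else 1,
                 binding = binding, elim = elim, intrinsic = intrinsic,
                 disposition = disposition, default_regimen = default_regimen,
                 ref_phys = ref_phys, qh = qh, fabs_fg = fabs_fg,
                 schedule = schedule, sim = sim),
            class = "drug_model")
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> %s | fu_ref %.3g | cl_ref %.3g L/h (%s anchor) | %s\n",
              x$name, x$binding$fu_ref, x$elim$cl_ref,
              x$elim$reference_population, x$default_regimen$route))
  invisible(x)
}

# Representative subject of the pre-pregnancy baseline physiology.
baseline_subject <- function(drug) {
  apply_scalers(drug$ref_phys, make_population("healthy"),
                subject_id = "baseline")
}

resolve_scalers <- function(population, gw = NULL) {
  if (inherits(population, "population_scalers")) return(population)
  make_population(population, gestational_week = gw)
}

#' Translate a drug model to a population (pipeline prediction)
#'
#' Representative-subject clearance, fraction unbound, and (for oral drugs)
#' bioavailability in the named population. The drug's anchored clearance
#' applies at the pre-pregnancy baseline: predictions for the anchor
#' population (and for `"healthy"`) return the anchored values unchanged,
#' reflecting the model-selection finding that the cancer-specific binding and
#' renal changes need not be carried into the clearance translation; pregnancy
#' targets are translated with the gestational-week scalers relative to that
#' baseline. Use [predict_cl()] directly for a fully general
#' target-vs-reference translation (as the decision workflow does for its
#' healthy-versus-cancer contrast).
#'
#' @param drug A [drug_model()].
#' @param population Population name or a [make_population()] object.
#' @param gw Gestational week for pregnancy populations.
#' @return An object of class `drug_prediction`: `cl`, `s`, `fu`, `f_oral`,
#'   per-pathway scaled intrinsic clearances, and the population's
#'   representative subject.
#' @export
#' @examples
#' drug <- load_drug("paclitaxel")
#' drug_predict(drug, "pregnancy_cyp2c8", gw = 32)
drug_predict <- function(drug, population, gw = NULL) {
  stopifnot(inherits(drug, "drug_model"))
  scalers <- resolve_scalers(population, gw)
  base <- baseline_subject(drug)
  rep_subject <- apply_scalers(drug$ref_phys, scalers)
  anchored <- scalers$name %in% c("healthy", drug$elim$reference_population)
  if (anchored) {
    pred <- list(cl = drug$elim$cl_ref,
                 cl_hepatic = drug$elim$cl_ref * (1 - drug$elim$f_renal),
                 cl_renal = drug$elim$cl_ref * drug$elim$f_renal,
                 s = drug$intrinsic$fu_clint_cyp3a4 +
                   drug$intrinsic$fu_clint_cyp2c8 +
                   drug$intrinsic$fu_clint_other,
                 fu = fu_at(drug$binding, scalers$albumin_scalar,
                            scalers$agp_scalar))
    scaled <- drug$intrinsic
  } else {
    p <- predict_cl(drug$elim, drug$intrinsic, drug$binding,
                    target = rep_subject, reference = base,
                    ref_phys = drug$ref_phys, qh = drug$qh)
    pred <- list(cl = p$cl, cl_hepatic = p$cl_hepatic, cl_renal = p$cl_renal,
                 s = p$s, fu = p$fu)
    r_fu <- p$fu / p$fu_reference
    scaled <- structure(list(
      fu_clint_cyp3a4 = drug$intrinsic$fu_clint_cyp3a4 * r_fu *
        rep_subject$cyp3a4_scalar / base$cyp3a4_scalar,
      fu_clint_cyp2c8 = drug$intrinsic$fu_clint_cyp2c8 * r_fu *
        rep_subject$cyp2c8_abundance / base$cyp2c8_abundance,
      fu_clint_other = drug$intrinsic$fu_clint_other * r_fu,
      cl_renal_ref = p$cl_renal), class = "intrinsic_clearances")
  }
  f_oral <- if (!is.null(drug$fabs_fg)) {
    oral_availability(pred$s, drug$qh, drug$fabs_fg)
  } else NULL
  structure(c(pred, list(f_oral = f_oral, population = scalers$name,
                         gestational_week = scalers$gestational_week,
                         scalers = scalers, intrinsic_scaled = scaled,
                         representative_subject = rep_subject)),
            class = "drug_prediction")
}

# Clearance for an individual subject of a population, relative to the
# population's representative prediction (captures sampled variability only).
subject_prediction <- function(drug, pred, subject) {
  p <- predict_cl(drug$elim, pred$intrinsic_scaled, drug$binding,
                  target = subject, reference = pred$representative_subject,
                  ref_phys = drug$ref_phys, qh = drug$qh)
  f_oral <- if (!is.null(drug$fabs_fg)) {
    oral_availability(p$s, drug$qh, drug$fabs_fg)
  } else NULL
  list(cl = p$cl, s = p$s, fu = p$fu, f_oral = f_oral)
}

build_disposition <- function(drug, cl, f_oral = NULL) {
  d <- drug$disposition
  disposition_model(v1 = d$v1, v2 = d$v2, q_inter = d$q_inter, cl = cl,
                    ka = d$ka, f_oral = f_oral)
}

#' Simulate a drug's concentration-time profile in a population
#'
#' Runs the translation pipeline ([drug_predict()]) and the kinetics engine
#' ([simulate_profile()]) for the representative subject (or a supplied
#' sampled subject) of a population.
#'
#' @param drug A [drug_model()].
#' @param population Population name or scalers.
#' @param gw Gestational week for pregnancy populations.
#' @param regimen Dosing regimen; defaults to the drug's.
#' @param subject Optional `subject_physiology` (sampled individual); its BSA
#'   resolves mg/m^2 doses.
#' @param prediction Optional precomputed [drug_predict()] result for the
#'   population (avoids recomputation in loops).
#' @param dt,t_end Simulation grid controls; default from the drug config.
#' @param grid Explicit output time grid, h (overrides `dt`/`t_end`); sparse
#'   grids are permitted, dosing breakpoints are handled internally.
#' @return A `conc_profile` with the prediction attached as attribute
#'   `"prediction"`.
#' @export
simulate_drug <- function(drug, population, gw = NULL, regimen = NULL,
                          subject = NULL, prediction = NULL, dt = NULL,
                          t_end = NULL, grid = NULL) {
  if (is.null(regimen)) regimen <- drug$default_regimen
  if (is.null(dt)) dt <- drug$sim$dt
  if (is.null(prediction)) prediction <- drug_predict(drug, population, gw)
  if (is.null(subject)) {
    cl <- prediction$cl
    f_oral <- prediction$f_oral
    bsa <- drug$ref_phys$bsa
  } else {
    sp <- subject_prediction(drug, prediction, subject)
    cl <- sp$cl
    f_oral <- sp$f_oral
    bsa <- subject$bsa
  }
  if (is.null(t_end)) {
    t_end <- if (regimen$n_doses > 1) regimen$n_doses * regimen$tau
             else if (!is.null(drug$sim$t_end)) drug$sim$t_end
             else 24
  }
  model <- build_disposition(drug, cl, f_oral)
  prof <- simulate_profile(model, regimen, bsa, grid = grid, dt = dt,
                           t_end = t_end, conc_scale = drug$conc_scale,
                           units = drug$units)
  attr(prof, "prediction") <- prediction
  prof
}

#' Representative-subject NCA summary for a drug in a population
#'
#' Simulates the representative subject and reduces the profile to the
#' exposure metrics the population comparisons use: Cmax, the drug-relevant
#' AUC (AUC to infinity for single intravenous doses; the 24-hour steady-state
#' window, two dosing intervals, for twice-daily oral dosing) and clearance.
#'
#' @inheritParams simulate_drug
#' @param cl_override Optional clearance, L/h, replacing the pipeline value
#'   (used by the workflow's raw population contrasts).
#' @return List with `cmax`, `auc`, `cl`, the full `pk_parameters`, and the
#'   underlying prediction.
#' @export
drug_nca <- function(drug, population, gw = NULL, regimen = NULL, dt = NULL,
                     cl_override = NULL) {
  if (is.null(regimen)) regimen <- drug$default_regimen
  prediction <- drug_predict(drug, population, gw)
  if (!is.null(cl_override)) {
    prediction$cl <- cl_override
    if (!is.null(drug$fabs_fg)) {
      # invert the well-stirred hepatic clearance to keep F consistent
      s <- drug$qh * cl_override / (drug$qh - cl_override)
      prediction$f_oral <- oral_availability(s, drug$qh, drug$fabs_fg)
    }
  }
  prof <- simulate_drug(drug, population, gw, regimen = regimen,
                        prediction = prediction, dt = dt)
  dose <- prof$dose_mg
  if (regimen$route == "oral") {
    win <- steady_state_window(prof, k = 2)
    pk <- compute_pk(win, dose_mg = dose, route = "oral",
                     auc_conversion = drug$conc_scale)
    auc <- .auc_trapezoid(win$times, win$conc)
  } else {
    pk <- compute_pk(prof, dose_mg = dose, route = regimen$route,
                     auc_conversion = drug$conc_scale)
    auc <- pk$auc_inf
  }
  list(cmax = pk$cmax, auc = auc, cl = pk$cl, pk = pk,
       prediction = prediction, dose_mg = dose)
}

#' Calibrate the central volume to a target peak concentration
#'
#' The disposition shape parameters are not reported for these drugs; v1 is
#' chosen so the simulated representative-subject Cmax matches a published
#' anchor, with the peripheral volume and inter-compartmental clearance fixed
#' at values giving a plausible terminal phase. For oral drugs the target is
#' the steady-state window Cmax.
#'
#' @param drug A [drug_model()] (its current `v1` is ignored).
#' @param target_cmax Target Cmax in the drug's concentration units.
#' @param population Population of the anchor (default the clearance anchor).
#' @param interval Search interval for v1, L.
#' @return Calibrated v1, L.
#' @export
calibrate_v1 <- function(drug, target_cmax,
                         population = drug$elim$reference_population,
                         interval = c(1, 500)) {
  f <- function(v1) {
    d <- drug
    d$disposition$v1 <- v1
    drug_nca(d, population, dt = 0.05)$cmax - target_cmax
  }
  stats::uniroot(f, interval, tol = 1e-4)$root
}
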