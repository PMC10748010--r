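#' Elimination model: pathway fractions and anchored total clearance
#'
#' Splits a drug's total plasma clearance, observed in a reference population,
#' into hepatic pathways (CYP3A4, CYP2C8, other hepatic routes such as biliary
#' excretion or conjugation) and renal filtration, by fraction metabolized /
#' excreted at reference conditions.
#'
#' @param fm_cyp3a4,fm_cyp2c8,fm_other_hepatic,f_renal Fractions of total
#'   clearance at reference; non-negative, summing to 1.
#' @param cl_ref Total plasma clearance in the reference population, L/h.
#' @param reference_population Name of the population whose observed PK
#'   anchors `cl_ref` (see [make_population()]).
#' @return An object of class `elimination_model`.
#' @export
elimination_model <- function(fm_cyp3a4, fm_cyp2c8, fm_other_hepatic, f_renal,
                              cl_ref, reference_population = "cancer") {
  fm <- c(fm_cyp3a4, fm_cyp2c8, fm_other_hepatic, f_renal)
  if (any(fm < 0)) stop("fm fractions must be >= 0")
  if (abs(sum(fm) - 1) > 1e-9) {
    stop(sprintf("fm fractions must sum to 1 (got %.10g)", sum(fm)))
  }
  if (cl_ref <= 0) stop("cl_ref must be strictly positive")
  reference_population <- match.arg(reference_population, .population_names)
  structure(list(fm_cyp3a4 = fm_cyp3a4, fm_cyp2c8 = fm_cyp2c8,
                 fm_other_hepatic = fm_other_hepatic, f_renal = f_renal,
                 cl_ref = cl_ref,
                 reference_population = reference_population),
            class = "elimination_model")
}

#' Back-calculate pathway intrinsic clearances (well-stirred inversion)
#'
#' Inverts the well-stirred liver model to recover the total `fu * CLint` term
#' implied by the reference hepatic clearance and hepatic blood flow:
#' `S = qh * CLh / (qh - CLh)` with `CLh = cl_ref * (1 - f_renal)`. The total
#' is split across CYP3A4 / CYP2C8 / other-hepatic in proportion to the fm
#' values renormalized among hepatic pathways. Renal clearance at reference is
#' `cl_ref * f_renal`.
#'
#' @param elim An [elimination_model()].
#' @param qh Hepatic blood flow, L/h.
#' @return An object of class `intrinsic_clearances` with fields
#'   `fu_clint_cyp3a4`, `fu_clint_cyp2c8`, `fu_clint_other` and
#'   `cl_renal_ref`, all L/h.
#' @export
#' @examples
#' e <- elimination_model(0.4, 0.4, 0.1, 0.1, cl_ref = 18.6)
#' back_calculate(e, qh = 90)
back_calculate <- function(elim, qh) {
  stopifnot(inherits(elim, "elimination_model"), qh > 0)
  cl_hepatic <- elim$cl_ref * (1 - elim$f_renal)
  if (cl_hepatic >= qh) {
    stop(sprintf(
      "extraction ratio >= 1: hepatic clearance %.3g exceeds blood flow %.3g",
      cl_hepatic, qh))
  }
  s_total <- if (cl_hepatic == 0) 0 else qh * cl_hepatic / (qh - cl_hepatic)
  fm_hep <- c(elim$fm_cyp3a4, elim$fm_cyp2c8, elim$fm_other_hepatic)
  w <- if (sum(fm_hep) == 0) c(0, 0, 0) else fm_hep / sum(fm_hep)
  structure(list(fu_clint_cyp3a4 = s_total * w[1],
                 fu_clint_cyp2c8 = s_total * w[2],
                 fu_clint_other = s_total * w[3],
                 cl_renal_ref = elim$cl_ref * elim$f_renal),
            class = "intrinsic_clearances")
}

#' Predict total clearance in a target physiology
#'
#' Scales each enzyme's `fu * CLint` term by the target/reference abundance
#' ratio and the fraction-unbound ratio (other hepatic routes by fu only),
#' recombines via the well-stirred model `CLh = qh * S / (qh + S)`, and scales
#' renal filtration clearance by the GFR and fu ratios. Fraction unbound in
#' each physiology follows from the binding model and the subject's protein
#' concentrations relative to the baseline `ref_phys`.
#'
#' @param elim An [elimination_model()].
#' @param intrinsic Result of [back_calculate()].
#' @param binding A [binding_model()] anchored at `ref_phys` protein levels.
#' @param target,reference `subject_physiology` objects (see
#'   [apply_scalers()]); `reference` is the subject under which `cl_ref` was
#'   observed.
#' @param ref_phys The [reference_physiology()] whose protein concentrations
#'   anchor the binding model.
#' @param qh Hepatic blood flow, L/h.
#' @return An object of class `cl_prediction`: list with `cl` (total, L/h),
#'   `cl_hepatic`, `cl_renal`, `s` (scaled total fu*CLint), and `fu` in the
#'   target physiology.
#' @export
predict_cl <- function(elim, intrinsic, binding, target, reference, ref_phys,
                       qh = ref_phys$hepatic_blood_flow) {
  stopifnot(inherits(elim, "elimination_model"),
            inherits(intrinsic, "intrinsic_clearances"),
            inherits(binding, "binding_model"),
            inherits(target, "subject_physiology"),
            inherits(reference, "subject_physiology"),
            inherits(ref_phys, "ref_physiology"))
  fu_t <- fu_at(binding, target$albumin / ref_phys$albumin,
                target$agp / ref_phys$agp)
  fu_r <- fu_at(binding, reference$albumin / ref_phys$albumin,
                reference$agp / ref_phys$agp)
  r_fu <- fu_t / fu_r
  r_3a4 <- target$cyp3a4_scalar / reference$cyp3a4_scalar
  r_2c8 <- target$cyp2c8_abundance / reference$cyp2c8_abundance
  s <- r_fu * (intrinsic$fu_clint_cyp3a4 * r_3a4 +
               intrinsic$fu_clint_cyp2c8 * r_2c8 +
               intrinsic$fu_clint_other)
  cl_h <- qh * s / (qh + s)
  cl_r <- intrinsic$cl_renal_ref * (target$gfr / reference$gfr) * r_fu
  structure(list(cl = cl_h + cl_r, cl_hepatic = cl_h, cl_renal = cl_r,
                 s = s, fu = fu_t, fu_reference = fu_r),
            class = "cl_prediction")
}

#' Oral availability under the well-stirred first-pass model
#'
#' `F = fabs_fg * qh / (qh + S)`, with `S` the (scaled) total `fu * CLint` of
#' the target physiology. Consistent with [predict_cl()] so that, for a fully
#' hepatically cleared drug, oral `AUC = F * Dose / CL = fabs_fg * Dose / S`.
#'
#' @param intrinsic_scaled_sum Total scaled `fu * CLint`, L/h (the `s` field of
#'   a [predict_cl()] result).
#' @param qh Hepatic blood flow, L/h.
#' @param fabs_fg Product of fraction absorbed and fraction escaping gut
#'   metabolism, in (0, 1].
#' @return Oral bioavailability fraction.
#' @export
oral_availability <- function(intrinsic_scaled_sum, qh, fabs_fg) {
  if (intrinsic_scaled_sum < 0 || qh <= 0) {
    stop("intrinsic clearance sum must be >= 0 and qh > 0")
  }
  if (fabs_fg <= 0 || fabs_fg > 1) stop("fabs_fg must lie in (0, 1]")
  fabs_fg * qh / (qh + intrinsic_scaled_sum)
}
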