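#' Reference (healthy, non-pregnant) physiology
#'
#' Baseline physiological values for the representative healthy adult on which
#' all population translations are anchored. Protein concentrations govern
#' plasma binding, enzyme abundances govern hepatic intrinsic clearance, GFR
#' governs renal filtration clearance, and BSA resolves body-surface-normalised
#' doses.
#'
#' @param albumin Plasma albumin, g/L. Healthy range 35-55.
#' @param agp Alpha-1-acid glycoprotein, g/L.
#' @param gfr Glomerular filtration rate, mL/min. Healthy range 60-140.
#' @param cyp3a4_scalar Relative hepatic CYP3A4 abundance (reference = 1).
#' @param cyp2c8_abundance Hepatic CYP2C8, pmol per mg microsomal protein.
#' @param hepatic_blood_flow L/h.
#' @param body_weight kg.
#' @param bsa Body surface area, m^2.
#' @return An object of class `ref_physiology`.
#' @export
#' @examples
#' reference_physiology()
reference_physiology <- function(albumin = 45, agp = 0.8, gfr = 110,
                                 cyp3a4_scalar = 1.0, cyp2c8_abundance = 24,
                                 hepatic_blood_flow = 90, body_weight = 70,
                                 bsa = 1.86) {
  vals <- c(albumin = albumin, agp = agp, gfr = gfr,
            cyp3a4_scalar = cyp3a4_scalar, cyp2c8_abundance = cyp2c8_abundance,
            hepatic_blood_flow = hepatic_blood_flow, body_weight = body_weight,
            bsa = bsa)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all reference physiology values must be strictly positive")
  }
  if (cyp3a4_scalar != 1.0) {
    stop("cyp3a4_scalar must be 1.0 at reference")
  }
  if (albumin < 35 || albumin > 55) stop("albumin outside healthy range 35-55 g/L")
  if (gfr < 60 || gfr > 140) stop("gfr outside healthy range 60-140 mL/min")
  structure(as.list(vals), class = "ref_physiology")
}

.population_names <- c("healthy", "cancer", "pregnancy", "pregnancy_cyp2c8")

# Gestational-week anchors for the pregnancy time-courses. Each profile is 1.0
# pre-pregnancy, reaches its 32-GW population value by linear interpolation,
# and CYP3A4 continues to 2.3-fold at term. Values are held flat beyond the
# last anchor.
.gw_anchors <- list(
  albumin = cbind(gw = c(0, 32), value = c(1.0, 0.75)),
  agp     = cbind(gw = c(0, 32), value = c(1.0, 0.70)),
  cyp3a4  = cbind(gw = c(0, 32, 40), value = c(1.0, 2.0, 2.3)),
  gfr     = cbind(gw = c(0, 32), value = c(1.0, 1.25))
)

#' Gestational-week profile of a pregnancy physiology scaler
#'
#' Piecewise-linear interpolation of the multiplicative change (relative to
#' pre-pregnancy) of a physiological parameter, through anchors at conception
#' (1.0), 32 gestational weeks (the population-model value) and, for CYP3A4,
#' 2.3-fold at term. CYP2C8 is flat throughout pregnancy: 1.0 under the default
#' pregnancy model and 2.5-fold under the CYP2C8-modified model.
#'
#' @param parameter One of "albumin", "agp", "cyp3a4", "cyp2c8", "gfr".
#' @param gestational_week Weeks, in `[0, 42]`. Values past the last anchor are
#'   held flat.
#' @param cyp2c8_induction Use the 2.5-fold induced CYP2C8 level (modified
#'   pregnancy model) for `parameter = "cyp2c8"` at `gestational_week > 0`.
#' @return Dimensionless scalar.
#' @export
#' @examples
#' gw_profile("cyp3a4", 32) # 2.0
#' gw_profile("cyp3a4", 16) # 1.5
gw_profile <- function(parameter, gestational_week, cyp2c8_induction = FALSE) {
  if (!is.numeric(gestational_week) || length(gestational_week) != 1 ||
      !is.finite(gestational_week) || gestational_week < 0 ||
      gestational_week > 42) {
    stop("gestational_week must be a single value in [0, 42]")
  }
  if (identical(parameter, "cyp2c8")) {
    return(if (cyp2c8_induction && gestational_week > 0) 2.5 else 1.0)
  }
  anchors <- .gw_anchors[[parameter]]
  if (is.null(anchors)) {
    stop("unknown parameter '", parameter,
         "'; expected albumin, agp, cyp3a4, cyp2c8 or gfr")
  }
  stats::approx(anchors[, "gw"], anchors[, "value"], xout = gestational_week,
                rule = 2)$y
}

#' Population physiology scalers
#'
#' Multiplicative modifiers of the reference physiology for the supported
#' population models: healthy (identity), cancer (lower albumin and GFR,
#' doubled AGP), pregnancy at a given gestational week, and the
#' CYP2C8-modified pregnancy model (additionally 2.5-fold hepatic CYP2C8).
#'
#' @param name One of "healthy", "cancer", "pregnancy", "pregnancy_cyp2c8".
#' @param gestational_week Required for (and only for) the pregnancy variants;
#'   weeks in (0, 42].
#' @param cancer_gfr_scalar GFR multiplier for the cancer model; default 0.65,
#'   the midpoint of the reported 30-40 percent decrease.
#' @return An object of class `population_scalers`.
#' @export
#' @examples
#' make_population("cancer")
#' make_population("pregnancy_cyp2c8", gestational_week = 32)
make_population <- function(name, gestational_week = NULL,
                            cancer_gfr_scalar = 0.65) {
  name <- match.arg(name, .population_names)
  pregnant <- name %in% c("pregnancy", "pregnancy_cyp2c8")
  if (pregnant) {
    if (is.null(gestational_week)) {
      stop("gestational_week must be supplied for pregnancy populations")
    }
    if (!is.numeric(gestational_week) || length(gestational_week) != 1 ||
        !is.finite(gestational_week) || gestational_week <= 0 ||
        gestational_week > 42) {
      stop("gestational_week must lie in (0, 42]")
    }
  } else if (!is.null(gestational_week)) {
    stop("gestational_week is only meaningful for pregnancy populations")
  }
  s <- switch(name,
    healthy = c(albumin = 1, agp = 1, cyp3a4 = 1, cyp2c8 = 1, gfr = 1),
    cancer = c(albumin = 0.85, agp = 2.0, cyp3a4 = 1, cyp2c8 = 1,
               gfr = cancer_gfr_scalar),
    {
      gw <- gestational_week
      c(albumin = gw_profile("albumin", gw),
        agp = gw_profile("agp", gw),
        cyp3a4 = gw_profile("cyp3a4", gw),
        cyp2c8 = gw_profile("cyp2c8", gw,
                            cyp2c8_induction = name == "pregnancy_cyp2c8"),
        gfr = gw_profile("gfr", gw))
    })
  structure(list(name = name,
                 gestational_week = if (pregnant) gestational_week else NULL,
                 albumin_scalar = unname(s["albumin"]),
                 agp_scalar = unname(s["agp"]),
                 cyp3a4_scalar = unname(s["cyp3a4"]),
                 cyp2c8_scalar = unname(s["cyp2c8"]),
                 gfr_scalar = unname(s["gfr"])),
            class = "population_scalers")
}

#' @export
print.population_scalers <- function(x, ...) {
  cat("<population_scalers>", x$name,
      if (!is.null(x$gestational_week)) sprintf("(GW %g)", x$gestational_week),
      "\n")
  cat(sprintf("  albumin %.3g | AGP %.3g | CYP3A4 %.3g | CYP2C8 %.3g | GFR %.3g\n",
              x$albumin_scalar, x$agp_scalar, x$cyp3a4_scalar,
              x$cyp2c8_scalar, x$gfr_scalar))
  invisible(x)
}

#' Realize a subject physiology from reference values and population scalers
#'
#' Field-wise multiplication of the reference physiology by the population
#' scalers. With no variability factors this is the deterministic
#' "representative subject" of the population.
#'
#' @param ref A [reference_physiology()] object.
#' @param scalers A [make_population()] object.
#' @param subject_id Identifier carried through to outputs.
#' @param variability_factors Optional named multipliers (names among
#'   `albumin`, `agp`, `cyp3a4`, `cyp2c8`) applied on top of the population
#'   scalers, used by [sample_subjects()].
#' @param bsa Optional per-subject body surface area override, m^2.
#' @return An object of class `subject_physiology` with realized values.
#' @export
apply_scalers <- function(ref, scalers, subject_id = "representative",
                          variability_factors = NULL, bsa = NULL) {
  stopifnot(inherits(ref, "ref_physiology"),
            inherits(scalers, "population_scalers"))
  vf <- function(p) {
    f <- variability_factors[[p]]
    if (is.null(f)) 1.0 else f
  }
  out <- list(
    subject_id = subject_id,
    albumin = ref$albumin * scalers$albumin_scalar * vf("albumin"),
    agp = ref$agp * scalers$agp_scalar * vf("agp"),
    gfr = ref$gfr * scalers$gfr_scalar,
    cyp3a4_scalar = ref$cyp3a4_scalar * scalers$cyp3a4_scalar * vf("cyp3a4"),
    cyp2c8_abundance = ref$cyp2c8_abundance * scalers$cyp2c8_scalar * vf("cyp2c8"),
    hepatic_blood_flow = ref$hepatic_blood_flow,
    body_weight = ref$body_weight,
    bsa = if (is.null(bsa)) ref$bsa else bsa,
    gestational_week = scalers$gestational_week,
    population = scalers$name
  )
  num <- unlist(out[c("albumin", "agp", "gfr", "cyp3a4_scalar",
                      "cyp2c8_abundance", "hepatic_blood_flow",
                      "body_weight", "bsa")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("realized subject physiology must be strictly positive")
  }
  structure(out, class = "subject_physiology")
}

#' Sample virtual subjects around a population's representative physiology
#'
#' Log-normal multiplicative inter-individual variability (median 1) on the
#' named parameters, plus optional uniform body-surface-area sampling. A CV of
#' zero reduces each parameter to the representative value.
#'
#' @param ref A [reference_physiology()] object.
#' @param scalers A [make_population()] object.
#' @param n Number of subjects.
#' @param variability Named list of coefficients of variation (fractions, e.g.
#'   `0.3`) for parameters among `albumin`, `agp`, `cyp3a4`, `cyp2c8`.
#' @param bsa_range Length-2 range for uniform BSA sampling, or `NULL` to keep
#'   the reference BSA.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG state.
#' @return List of `subject_physiology` objects.
#' @export
#' @examples
#' s <- sample_subjects(reference_physiology(), make_population("cancer"),
#'                      n = 3, variability = list(cyp3a4 = 0.3), seed = 1)
sample_subjects <- function(ref, scalers, n,
                            variability = list(cyp3a4 = 0.3, cyp2c8 = 0.3,
                                               albumin = 0.2, agp = 0.2),
                            bsa_range = NULL, seed = NULL) {
  stopifnot(n >= 1)
  cvs <- unlist(variability)
  if (length(cvs) && any(cvs < 0)) stop("variability CVs must be >= 0")
  unknown <- setdiff(names(variability), c("albumin", "agp", "cyp3a4", "cyp2c8"))
  if (length(unknown)) stop("unknown variability parameter(s): ",
                            paste(unknown, collapse = ", "))
  draw <- function() {
    lapply(seq_len(n), function(i) {
      facs <- lapply(variability, function(cv) {
        if (cv == 0) 1.0 else exp(stats::rnorm(1, 0, sqrt(log(1 + cv^2))))
      })
      bsa <- if (is.null(bsa_range)) NULL else stats::runif(1, bsa_range[1], bsa_range[2])
      apply_scalers(ref, scalers, subject_id = sprintf("S%03d", i),
                    variability_factors = facs, bsa = bsa)
    })
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
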