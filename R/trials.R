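#' Run a virtual clinical trial
#'
#' Samples virtual subjects around the population's representative physiology
#' (log-normal inter-individual variability on enzyme abundances and binding
#' proteins, uniform body surface area), simulates each subject, runs
#' noncompartmental analysis, and aggregates PK parameters and the
#' concentration band across all subjects. Deterministic under a fixed seed.
#'
#' @param drug A [drug_model()].
#' @param population Population name or scalers.
#' @param gw Gestational week for pregnancy populations.
#' @param n_trials,n_subjects Trial design (default 10 trials of 10 subjects).
#' @param seed Integer seed.
#' @param variability Named CV list for [sample_subjects()]; default 30
#'   percent on enzyme scalars, 20 percent on binding proteins.
#' @param bsa_range Uniform BSA range, m^2, or `NULL` for fixed BSA.
#' @param dt Simulation grid spacing, h.
#' @return An object of class `trial_summary`: `params` (mean and 5th/95th
#'   percentile of Cmax, AUC, CL over subjects), `band` (per-timepoint mean
#'   and 5th-95th percentile concentrations), and the design.
#' @export
run_virtual_trial <- function(drug, population, gw = NULL, n_trials = 10,
                              n_subjects = 10, seed = 1,
                              variability = list(cyp3a4 = 0.3, cyp2c8 = 0.3,
                                                 albumin = 0.2, agp = 0.2),
                              bsa_range = c(1.6, 2.0), dt = 0.1) {
  stopifnot(inherits(drug, "drug_model"))
  pred <- drug_predict(drug, population, gw)
  regimen <- drug$default_regimen
  oral <- regimen$route == "oral"
  run <- function() {
    res <- vector("list", n_trials * n_subjects)
    k <- 0
    for (trial in seq_len(n_trials)) {
      subjects <- sample_subjects(drug$ref_phys, pred$scalers, n_subjects,
                                  variability = variability,
                                  bsa_range = bsa_range, seed = NULL)
      for (sub in subjects) {
        k <- k + 1
        prof <- simulate_drug(drug, population, gw, subject = sub,
                              prediction = pred, dt = dt)
        if (oral) {
          win <- steady_state_window(prof, k = 2)
          pk <- compute_pk(win, dose_mg = prof$dose_mg, route = "oral",
                           auc_conversion = drug$conc_scale)
          auc <- .auc_trapezoid(win$times, win$conc)
          conc <- prof$conc
        } else {
          pk <- compute_pk(prof, dose_mg = prof$dose_mg, route = regimen$route,
                           auc_conversion = drug$conc_scale)
          auc <- pk$auc_inf
          conc <- prof$conc
        }
        res[[k]] <- list(trial = trial, cmax = pk$cmax, auc = auc, cl = pk$cl,
                         times = prof$times, conc = conc)
      }
    }
    res
  }
  res <- with_preserved_seed(seed, run())

  vals <- function(what) vapply(res, `[[`, numeric(1), what)
  qs <- function(x) stats::quantile(x, c(0.05, 0.95), names = FALSE)
  params <- do.call(rbind, lapply(c("cmax", "auc", "cl"), function(p) {
    v <- vals(p)
    data.frame(parameter = p, mean = mean(v), p05 = qs(v)[1], p95 = qs(v)[2])
  }))
  # all subjects share the representative grid (identical regimen and dt)
  times <- res[[1]]$times
  cmat <- vapply(res, `[[`, numeric(length(times)), "conc")
  band <- data.frame(time = times,
                     mean = rowMeans(cmat),
                     p05 = apply(cmat, 1, stats::quantile, 0.05, names = FALSE),
                     p95 = apply(cmat, 1, stats::quantile, 0.95, names = FALSE))
  structure(list(params = params, band = band, n_trials = n_trials,
                 n_subjects = n_subjects, seed = seed,
                 population = pred$population, gestational_week = gw,
                 drug = drug$name, units = drug$units),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> %s in %s: %d trials x %d subjects (seed %s)\n",
              x$drug, x$population, x$n_trials, x$n_subjects, x$seed))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Compare predicted against observed PK parameters
#'
#' Predicted-to-observed ratios with the standard acceptability flags: the
#' two-fold criterion (ratio in `[0.5, 2]`) and the tighter 25 percent bound
#' (ratio in `[0.75, 1.25]`).
#'
#' @param predicted A `pk_parameters`, `trial_summary` (means used), named
#'   list, or single number.
#' @param observed A named list / `pk_parameters` with the matching
#'   parameters, or a single number.
#' @return Data frame with `parameter`, `predicted`, `observed`, `ratio`,
#'   `within_twofold`, `within_25pct`.
#' @export
#' @examples
#' evaluate_prediction(list(auc = 11.8), list(auc = 8.7))
evaluate_prediction <- function(predicted, observed) {
  as_named <- function(x) {
    if (inherits(x, "trial_summary")) {
      stats::setNames(as.list(x$params$mean), x$params$parameter)
    } else if (inherits(x, "pk_parameters")) {
      list(cmax = x$cmax,
           auc = if (is.finite(x$auc_tau)) x$auc_tau else x$auc_inf,
           cl = x$cl)
    } else if (is.numeric(x) && is.null(names(x)) && length(x) == 1) {
      list(value = x)
    } else as.list(x)
  }
  p <- as_named(predicted)
  o <- as_named(observed)
  shared <- intersect(names(p), names(o))
  shared <- shared[vapply(shared, function(k) {
    is.numeric(p[[k]]) && is.numeric(o[[k]]) && is.finite(p[[k]]) && is.finite(o[[k]])
  }, logical(1))]
  if (!length(shared)) stop("no shared numeric parameters to compare")
  rows <- lapply(shared, function(k) {
    if (o[[k]] == 0) stop("observed ", k, " is zero")
    r <- p[[k]] / o[[k]]
    data.frame(parameter = k, predicted = p[[k]], observed = o[[k]], ratio = r,
               within_twofold = r >= 0.5 & r <= 2.0,
               within_25pct = r >= 0.75 & r <= 1.25)
  })
  do.call(rbind, rows)
}

#' Fraction of observations inside the 90 percent prediction interval
#'
#' Interpolates a virtual-trial band (5th-95th percentiles) to the
#' observation times and returns the fraction of points falling inside.
#'
#' @param obs_times,obs_conc Observed time points (h) and concentrations.
#' @param band A `trial_summary`, or a data frame with `time`, `p05`, `p95`.
#' @return Fraction in `[0, 1]`.
#' @export
pi_coverage <- function(obs_times, obs_conc, band) {
  if (inherits(band, "trial_summary")) band <- band$band
  stopifnot(length(obs_times) == length(obs_conc))
  if (min(obs_times) < min(band$time) - 1e-9 ||
      max(obs_times) > max(band$time) + 1e-9) {
    stop("observations fall outside the simulated time span")
  }
  lo <- stats::approx(band$time, band$p05, xout = obs_times)$y
  hi <- stats::approx(band$time, band$p95, xout = obs_times)$y
  mean(obs_conc >= lo & obs_conc <= hi)
}

#' Population exposure comparison (ratio table)
#'
#' Cmax and AUC ratios of population A over population B, with
#' percent-lower phrasing, from the representative-subject pipeline
#' (deterministic) or from virtual-trial means.
#'
#' @param drug A [drug_model()].
#' @param pop_a,pop_b Population names or scalers.
#' @param gw_a,gw_b Gestational weeks where applicable.
#' @param mode `"representative"` (default) or `"trial"`.
#' @param seed,n_trials,n_subjects Trial design for `mode = "trial"`.
#' @return Data frame with `parameter`, `a`, `b`, `ratio` (a/b), `pct_lower`.
#' @export
#' @examples
#' drug <- load_drug("acalabrutinib")
#' population_comparison(drug, "pregnancy", "cancer", gw_a = 32)
population_comparison <- function(drug, pop_a, pop_b, gw_a = NULL, gw_b = NULL,
                                  mode = c("representative", "trial"),
                                  seed = 1, n_trials = 10, n_subjects = 10) {
  mode <- match.arg(mode)
  get <- function(pop, gw, s) {
    if (mode == "representative") {
      n <- drug_nca(drug, pop, gw)
      list(cmax = n$cmax, auc = n$auc, cl = n$cl)
    } else {
      tr <- run_virtual_trial(drug, pop, gw, n_trials = n_trials,
                              n_subjects = n_subjects, seed = s)
      stats::setNames(as.list(tr$params$mean), tr$params$parameter)
    }
  }
  a <- get(pop_a, gw_a, seed)
  b <- get(pop_b, gw_b, seed + 1)
  do.call(rbind, lapply(c("cmax", "auc"), function(p) {
    data.frame(parameter = p, a = a[[p]], b = b[[p]], ratio = a[[p]] / b[[p]],
               pct_lower = 100 * (1 - a[[p]] / b[[p]]))
  }))
}

#' Sensitivity of predicted PK to a single physiological parameter
#'
#' Recomputes the representative-subject clearance, AUC and Cmax over a grid
#' of multipliers applied to one physiological scaler on top of a base
#' population, using the fully general clearance translation.
#'
#' @param drug A [drug_model()].
#' @param parameter One of `"cyp3a4"`, `"cyp2c8"`, `"albumin"`, `"agp"`,
#'   `"gfr"`.
#' @param multipliers Positive multiplier grid.
#' @param population Base population (default `"healthy"`).
#' @param gw Gestational week where applicable.
#' @return Data frame with `multiplier`, `cl`, `auc`, `cmax`.
#' @export
sensitivity_analysis <- function(drug, parameter, multipliers,
                                 population = "healthy", gw = NULL) {
  parameter <- match.arg(parameter,
                         c("cyp3a4", "cyp2c8", "albumin", "agp", "gfr"))
  if (any(multipliers <= 0)) stop("multipliers must be strictly positive")
  base_scalers <- resolve_scalers(population, gw)
  base <- baseline_subject(drug)
  rows <- lapply(multipliers, function(m) {
    s <- base_scalers
    field <- paste0(parameter, "_scalar")
    s[[field]] <- s[[field]] * m
    target <- apply_scalers(drug$ref_phys, s)
    p <- predict_cl(drug$elim, drug$intrinsic, drug$binding, target, base,
                    drug$ref_phys, drug$qh)
    n <- drug_nca(drug, s, cl_override = p$cl)
    data.frame(multiplier = m, cl = p$cl, auc = n$auc, cmax = n$cmax)
  })
  do.call(rbind, rows)
}

#' Population-model selection workflow
#'
#' Operationalizes the stepwise selection of a population model for pregnant
#' patients with cancer:
#' \enumerate{
#'   \item Contrast the healthy and cancer representative predictions (full
#'     physiological translation). If all parameter ratios fall within
#'     0.8-1.25 the cancer-specific changes are deemed negligible for this
#'     drug and the pregnancy models are built on the common baseline.
#'   \item Predict with the default pregnancy model; if AUC and CL are within
#'     25 percent of every observed pregnant dataset, select it.
#'   \item Otherwise apply the CYP2C8-modified pregnancy model and re-evaluate.
#' }
#' Cmax is reported in the audit trail but, like the source analysis, the
#' accept/reject decision rests on AUC and CL. If no model passes, the
#' best-fitting model is returned flagged as not validated.
#'
#' @param drug A [drug_model()].
#' @param obs_pregnant A single observed record (named list with `auc`, `cl`,
#'   optionally `cmax`) or a list of such records (e.g. several studies, as
#'   from [load_fixture()]); all must pass.
#' @param gw Gestational week of the prediction (default 32).
#' @param obs_nonpregnant Optional observed non-pregnant record; compared
#'   against the anchor prediction in the audit trail (two-fold criterion).
#' @return An object of class `workflow_result`: `selected` (population
#'   name), `validated` (logical), and `audit` (list of step records with
#'   comparison tables).
#' @export
decision_workflow <- function(drug, obs_pregnant, gw = 32,
                              obs_nonpregnant = NULL) {
  stopifnot(inherits(drug, "drug_model"))
  if (!is.null(obs_pregnant$auc)) obs_pregnant <- list(obs_pregnant)
  audit <- list()

  # Step 1: healthy vs cancer representative predictions (raw translation).
  base <- baseline_subject(drug)
  cancer <- apply_scalers(drug$ref_phys, make_population("cancer"))
  p_cancer <- predict_cl(drug$elim, drug$intrinsic, drug$binding, cancer, base,
                         drug$ref_phys, drug$qh)
  nca_h <- drug_nca(drug, "healthy")
  nca_c <- drug_nca(drug, "cancer", cl_override = p_cancer$cl)
  cmp1 <- evaluate_prediction(list(cmax = nca_h$cmax, auc = nca_h$auc,
                                   cl = nca_h$cl),
                              list(cmax = nca_c$cmax, auc = nca_c$auc,
                                   cl = nca_c$cl))
  equivalent <- all(cmp1$ratio >= 0.8 & cmp1$ratio <= 1.25)
  audit$healthy_vs_cancer <- list(comparison = cmp1, equivalent = equivalent)
  if (!is.null(obs_nonpregnant)) {
    anchor_nca <- drug_nca(drug, drug$elim$reference_population)
    audit$anchor_vs_observed <- evaluate_prediction(
      list(cmax = anchor_nca$cmax, auc = anchor_nca$auc, cl = anchor_nca$cl),
      obs_nonpregnant)
  }

  check_model <- function(population) {
    n <- drug_nca(drug, population, gw = gw)
    cmps <- lapply(obs_pregnant, function(obs) {
      evaluate_prediction(list(cmax = n$cmax, auc = n$auc, cl = n$cl), obs)
    })
    gating <- do.call(rbind, cmps)
    gating <- gating[gating$parameter %in% c("auc", "cl"), ]
    list(population = population, prediction = n, comparisons = cmps,
         pass = all(gating$within_25pct),
         worst = max(abs(log(gating$ratio))))
  }

  step2 <- check_model("pregnancy")
  audit$default_pregnancy <- step2
  if (step2$pass) {
    return(structure(list(selected = "pregnancy", validated = TRUE,
                          audit = audit), class = "workflow_result"))
  }
  step3 <- check_model("pregnancy_cyp2c8")
  audit$modified_pregnancy <- step3
  if (step3$pass) {
    return(structure(list(selected = "pregnancy_cyp2c8", validated = TRUE,
                          audit = audit), class = "workflow_result"))
  }
  best <- if (step2$worst <= step3$worst) "pregnancy" else "pregnancy_cyp2c8"
  structure(list(selected = best, validated = FALSE, audit = audit),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf("<workflow_result> selected: %s (%s)\n", x$selected,
              if (x$validated) "validated" else "NOT validated"))
  invisible(x)
}
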