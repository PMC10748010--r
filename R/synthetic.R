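#' Generate a synthetic sparse "observed" clinical dataset
#'
#' Emulates the statistical structure of sparse clinical concentration-time
#' data: per-subject physiology with log-normal inter-individual variability
#' on the clearance-governing enzyme abundances, simulation of the dosing
#' regimen, sampling at a sparse schedule, and log-normal residual
#' (assay/within-subject) error. The generating truth is stored alongside the
#' data for parameter-recovery testing.
#'
#' @param drug A [drug_model()].
#' @param population Population name or scalers.
#' @param gw Gestational week for pregnancy populations.
#' @param n_subjects Number of subjects.
#' @param iiv_cv Inter-individual CV (fraction) on CYP3A4 and CYP2C8
#'   abundance.
#' @param residual_cv Residual (multiplicative, median-1 log-normal) CV.
#' @param schedule Sampling times, h; defaults to the drug's bundled schedule.
#'   For oral steady-state regimens the schedule is relative to the final
#'   dose.
#' @param seed Integer seed.
#' @return An object of class `observed_dataset`: `data` (long data frame),
#'   `truth` (generating representative and per-subject clearances), the
#'   schedule and seed.
#' @export
#' @examples
#' drug <- load_drug("docetaxel")
#' ds <- generate_observed(drug, "cancer", n_subjects = 5, seed = 3)
generate_observed <- function(drug, population, gw = NULL, n_subjects,
                              iiv_cv = 0.30, residual_cv = 0.20,
                              schedule = drug$schedule, seed = 1) {
  stopifnot(inherits(drug, "drug_model"), n_subjects >= 1)
  if (iiv_cv < 0 || residual_cv < 0) stop("CVs must be >= 0")
  if (is.null(schedule) || !length(schedule)) stop("schedule must be non-empty")
  regimen <- drug$default_regimen
  offset <- if (regimen$route == "oral") (regimen$n_doses - 1) * regimen$tau else 0
  t_end <- if (regimen$n_doses > 1) regimen$n_doses * regimen$tau
           else drug$sim$t_end %||% 24
  times <- offset + schedule
  if (max(times) > t_end + 1e-9) {
    stop("sampling schedule extends beyond the simulated time span")
  }
  pred <- drug_predict(drug, population, gw)
  grid <- sort(unique(c(0, times)))

  build <- function() {
    subjects <- sample_subjects(drug$ref_phys, pred$scalers, n_subjects,
                                variability = list(cyp3a4 = iiv_cv,
                                                   cyp2c8 = iiv_cv),
                                bsa_range = NULL, seed = NULL)
    rows <- list()
    subject_cl <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      sub <- subjects[[i]]
      sp <- subject_prediction(drug, pred, sub)
      subject_cl[i] <- sp$cl
      prof <- simulate_drug(drug, population, gw, subject = sub,
                            prediction = pred, grid = grid)
      conc <- stats::approx(prof$times, prof$conc, xout = times)$y
      eps <- if (residual_cv == 0) rep(1, length(times)) else {
        exp(stats::rnorm(length(times), 0, sqrt(log(1 + residual_cv^2))))
      }
      rows[[i]] <- data.frame(subject_id = sub$subject_id, time_h = schedule,
                              conc = conc * eps, units = drug$units)
    }
    list(data = do.call(rbind, rows), subject_cl = subject_cl,
         dose_mg = resolve_dose(regimen, drug$ref_phys$bsa))
  }
  out <- with_preserved_seed(seed, build())
  structure(list(data = out$data,
                 truth = list(cl_representative = pred$cl,
                              subject_cl = out$subject_cl,
                              population = pred$population,
                              gestational_week = gw,
                              iiv_cv = iiv_cv, residual_cv = residual_cv),
                 schedule = schedule, schedule_offset = offset,
                 dose_mg = out$dose_mg, route = regimen$route,
                 tau = regimen$tau, drug = drug$name, seed = seed),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf("<observed_dataset> %s (%s), %d subjects x %d samples, seed %s\n",
              x$drug, x$truth$population,
              length(unique(x$data$subject_id)), length(x$schedule), x$seed))
  invisible(x)
}

#' Recover clearance from a synthetic observed dataset
#'
#' Per-subject noncompartmental analysis of the sparse profiles (a zero
#' pre-dose concentration is prepended for intravenous dosing), arithmetic
#' mean clearance across subjects, and back-calculation of the implied
#' pathway intrinsic clearances using the drug's pathway fractions. Closes
#' the calibrate-then-translate loop: with low noise the generating clearance
#' is recovered.
#'
#' @param dataset An [generate_observed()] result.
#' @param drug The generating [drug_model()].
#' @return List with `mean_cl`, `subject_cl`, `cv`, `n`, `low_confidence`
#'   (fewer than 5 subjects or CV above 50 percent), `truth_cl`, and
#'   `intrinsic` (back-calculated at the recovered mean).
#' @export
recover_parameters <- function(dataset, drug) {
  stopifnot(inherits(dataset, "observed_dataset"), inherits(drug, "drug_model"))
  ids <- unique(dataset$data$subject_id)
  n <- length(ids)
  if (n < 5) {
    warning("fewer than 5 subjects: clearance recovery is low-confidence")
  }
  oral <- dataset$route == "oral"
  cls <- vapply(ids, function(id) {
    d <- dataset$data[dataset$data$subject_id == id, ]
    times <- d$time_h
    conc <- d$conc
    if (!oral) {
      times <- c(0, times)
      conc <- c(0, conc)
    }
    prof <- list(times = times, conc = conc, units = dataset$units)
    pk <- compute_pk(prof, dose_mg = dataset$dose_mg,
                     route = if (oral) "iv_infusion" else dataset$route,
                     auc_conversion = if (oral) 1000 else 1)
    if (oral) {
      # apparent CL/F over the sampled steady-state interval
      dataset$dose_mg / .auc_trapezoid(times, conc) * 1000
    } else {
      pk$cl
    }
  }, numeric(1))
  mean_cl <- mean(cls)
  cv <- stats::sd(cls) / mean_cl
  elim_rec <- drug$elim
  elim_rec$cl_ref <- mean_cl
  list(mean_cl = mean_cl, subject_cl = unname(cls), cv = cv, n = n,
       low_confidence = n < 5 || (is.finite(cv) && cv > 0.5),
       truth_cl = dataset$truth$cl_representative,
       intrinsic = back_calculate(elim_rec, drug$qh))
}

# md5 pin of the bundled observed-PK fixture file
.fixture_md5 <- "e7f34f8bc712f6bfc8f4e2b33fc24349"

#' Load a packaged observed-PK fixture
#'
#' Published pregnant- and non-pregnant-patient PK summaries used to verify
#' the population models: paclitaxel and docetaxel pregnant-patient studies
#' (van Hasselt 2014, Janssen 2021) and the acalabrutinib non-pregnant cancer
#' study (Byrd 2016). The fixture file is read-only and checksum-pinned.
#'
#' @param name Fixture name, e.g. `"paclitaxel_vanhasselt"`; `NULL` lists the
#'   available names.
#' @return Named list with the study's PK record (`cmax`, `auc`, `cl`, `n`,
#'   `gw` as available), or a character vector of names.
#' @export
#' @examples
#' load_fixture("docetaxel_janssen")$auc # 2.3
load_fixture <- function(name = NULL) {
  path <- system.file("extdata", "fixtures", "observed_pk.json",
                      package = "gravipk")
  if (!nzchar(path)) stop("fixture file not installed")
  if (unname(tools::md5sum(path)) != .fixture_md5) {
    stop("fixture file has been modified (md5 mismatch)")
  }
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(name)) return(names(fx))
  if (!name %in% names(fx)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fx), collapse = ", "))
  }
  fx[[name]]
}
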