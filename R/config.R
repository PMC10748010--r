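.drug_config_keys <- c("name", "units", "binding", "elimination",
                       "disposition", "default_regimen", "fabs_fg",
                       "schedule", "sim")

#' Load and validate a drug configuration file
#'
#' Reads a YAML (or JSON) drug configuration, rejects unknown keys, and checks
#' component invariants (fraction-metabolized sum, positive parameters). The
#' configuration stores published anchors, not derived constants: the
#' reference clearance is recomputed from the anchor dose and AUC on load, and
#' a two-protein binding partition given as a calibration block is solved with
#' [solve_partition()].
#'
#' @param path Path to the configuration file.
#' @return Validated configuration list.
#' @export
load_drug_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .drug_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("name", "units", "binding", "elimination", "disposition",
                "default_regimen")) {
    if (is.null(cfg[[key]])) stop("config is missing required key '", key, "'")
  }
  fm <- cfg$elimination
  fm_sum <- fm$fm_cyp3a4 + fm$fm_cyp2c8 + fm$fm_other_hepatic + fm$f_renal
  if (abs(fm_sum - 1) > 1e-9) {
    stop(sprintf("invalid 'fm': pathway fractions sum to %.10g, expected 1", fm_sum))
  }
  if (is.null(fm$anchor) || is.null(fm$anchor$dose_mg)) {
    stop("elimination block needs an anchor with dose_mg and an AUC value")
  }
  cfg
}

#' Write a drug configuration to YAML
#'
#' @param cfg Configuration list (as from [load_drug_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Names of the drug models bundled with the package
#'
#' @return Character vector of config names usable with [load_drug()].
#' @export
bundled_drugs <- function() {
  sub("[.]yaml$", "", dir(system.file("extdata", "drugs", package = "gravipk"),
                          pattern = "[.]yaml$"))
}

#' Load a bundled or external drug model
#'
#' Builds a full [drug_model()] from a configuration: solves the binding
#' partition if given as a calibration block, derives the anchored reference
#' clearance from the published dose/AUC anchor (intravenous drugs:
#' `cl_ref = dose / AUC`; oral drugs: the total intrinsic clearance implied by
#' `AUC_tau = fabs_fg * dose / S`, folded through the well-stirred liver), and
#' back-calculates pathway intrinsic clearances.
#'
#' @param name Bundled drug name (see [bundled_drugs()]) or a path to a
#'   configuration file.
#' @param ref_phys Reference physiology; defaults to [reference_physiology()].
#' @return A [drug_model()].
#' @export
#' @examples
#' load_drug("docetaxel")
load_drug <- function(name, ref_phys = reference_physiology()) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "drugs", paste0(name, ".yaml"), package = "gravipk")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown drug '", name, "'; bundled: ",
         paste(bundled_drugs(), collapse = ", "))
  }
  cfg <- load_drug_config(path)

  b <- cfg$binding
  binding <- if (!is.null(b$calibrate)) {
    loads <- solve_partition(b$fu_ref, b$calibrate$fu_alt,
                             b$calibrate$albumin_scalar,
                             b$calibrate$agp_scalar)
    binding_model(b$fu_ref, loads[["load_albumin"]], loads[["load_agp"]])
  } else {
    binding_model(b$fu_ref, b$load_albumin, b$load_agp %||% 0)
  }

  e <- cfg$elimination
  anchor <- e$anchor
  qh <- ref_phys$hepatic_blood_flow
  oral <- identical(cfg$default_regimen$route, "oral")
  cl_ref <- if (!is.null(anchor$auc_mg_h_l)) {
    anchor$dose_mg / anchor$auc_mg_h_l
  } else if (!is.null(anchor$auc_0_24_ng_h_ml)) {
    # steady-state oral anchor: AUC per interval, in mg*h/L
    auc_tau <- anchor$auc_0_24_ng_h_ml / (anchor$n_intervals %||% 2) / 1000
    s <- cfg$fabs_fg * anchor$dose_mg / auc_tau
    qh * s / (qh + s)
  } else {
    stop("anchor must provide auc_mg_h_l or auc_0_24_ng_h_ml")
  }
  elim <- elimination_model(e$fm_cyp3a4, e$fm_cyp2c8, e$fm_other_hepatic,
                            e$f_renal, cl_ref = cl_ref,
                            reference_population = e$reference_population %||% "cancer")

  r <- cfg$default_regimen
  regimen <- dosing_regimen(route = r$route, dose_mg = r[["dose_mg"]],
                            dose_mg_per_m2 = r[["dose_mg_per_m2"]],
                            infusion_duration = r$infusion_duration,
                            tau = r$tau, n_doses = r$n_doses %||% 1)

  drug_model(name = cfg$name, binding = binding, elim = elim,
             disposition = cfg$disposition, default_regimen = regimen,
             ref_phys = ref_phys, units = cfg$units, fabs_fg = cfg$fabs_fg,
             schedule = cfg$schedule,
             sim = cfg$sim %||% list(dt = 0.05, t_end = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a concentration profile (or observed dataset) as CSV
#'
#' Comma-separated, header row, dot decimal; columns `subject_id`, `time_h`,
#' `conc`, `units`.
#'
#' @param x A `conc_profile`, or a data frame with those columns.
#' @param path Output path.
#' @param subject_id Identifier used when `x` is a single profile.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path, subject_id = "representative") {
  df <- if (inherits(x, "conc_profile")) {
    cbind(subject_id = subject_id, as.data.frame(x))
  } else as.data.frame(x)
  stopifnot(all(c("subject_id", "time_h", "conc", "units") %in% names(df)))
  utils::write.csv(df[, c("subject_id", "time_h", "conc", "units")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a concentration CSV
#'
#' @param path CSV with columns `subject_id`, `time_h`, `conc`, `units`.
#' @return Data frame.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_h", "conc", "units")
  if (!all(need %in% names(df))) {
    stop("profile CSV must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' Build a run manifest for reproducibility
#'
#' @param command Character description of the invocation.
#' @param inputs Paths of configuration/input files (hashed with md5).
#' @param seed Seed used, or `NULL`.
#' @return List with tool version, input hashes, seed, timestamp and command.
#' @export
run_manifest <- function(command, inputs = character(), seed = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(tool = "gravipk",
       version = as.character(utils::packageVersion("gravipk")),
       command = command, config_hashes = hashes, seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a manifest (or any summary list) as JSON
#'
#' @param x List to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
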