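# Trapezoidal AUC. "lin-up-log-down" uses the log-trapezoid on strictly
# decreasing positive segments, the standard NCA convention; "linear" is plain
# trapezoids (exposed for sensitivity).
.auc_trapezoid <- function(times, conc, method = c("lin-up-log-down", "linear")) {
  method <- match.arg(method)
  dt <- diff(times)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  lin <- dt * (c1 + c2) / 2
  if (method == "lin-up-log-down") {
    down <- c2 < c1 & c2 > 0 & c1 > 0
    lin[down] <- dt[down] * (c1[down] - c2[down]) / log(c1[down] / c2[down])
  }
  sum(lin)
}

# Terminal slope by log-linear regression, choosing among trailing windows of
# 3-6 points after Tmax by best adjusted R-squared.
.fit_lambda_z <- function(times, conc) {
  imax <- which.max(conc)
  idx <- which(seq_along(conc) > imax & conc > 0)
  if (length(idx) < 3) stop("too few post-peak positive points for lambda_z")
  best <- NULL
  for (np in 3:min(6, length(idx))) {
    i <- utils::tail(idx, np)
    fit <- stats::lm(log(conc[i]) ~ times[i])
    # noiseless simulated data fit exactly; silence the perfect-fit warning
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || (is.finite(r2) && r2 > best$r2 + 1e-12)) {
      best <- list(lambda = -unname(stats::coef(fit)[2]), r2 = r2, n = np)
    }
  }
  if (!is.finite(best$lambda) || best$lambda <= 0) {
    stop("lambda_z estimation failed: terminal slope is not negative")
  }
  best
}

#' Noncompartmental analysis of a concentration-time profile
#'
#' Computes Cmax, Tmax, AUC to the last point (linear-up/log-down trapezoid),
#' the terminal slope lambda_z (log-linear regression over the best trailing
#' 3-6 point window by adjusted R-squared), extrapolated AUC to infinity, the
#' interval AUC when the profile is a steady-state dosing window, and
#' clearance: `dose / AUC_inf` for intravenous dosing, or apparent
#' `dose / AUC_tau` for oral dosing at steady state.
#'
#' @param profile A `conc_profile` (or list with `times` and `conc`).
#' @param dose_mg Dose amount associated with the profile; defaults to the
#'   profile's resolved dose. For a steady-state window it is the dose per
#'   interval.
#' @param route `"iv_infusion"` or `"oral"`; defaults to the profile's.
#' @param method AUC method, `"lin-up-log-down"` (default) or `"linear"`.
#' @param auc_conversion Multiplier applied to dose/AUC ratios so clearance is
#'   reported in L/h when concentrations are not in mg/L (e.g. `1000` for
#'   ng/mL profiles).
#' @return An object of class `pk_parameters`: `cmax`, `tmax`, `auc_last`,
#'   `auc_inf`, `auc_tau` (when a dosing window), `cl`, `lambda_z`,
#'   `n_lambda_points`.
#' @export
#' @examples
#' t <- seq(0, 24, 0.1)
#' p <- list(times = t, conc = 10 * exp(-0.5 * t))
#' compute_pk(p, dose_mg = 100, route = "iv_infusion")
compute_pk <- function(profile, dose_mg = profile$dose_mg,
                       route = profile$route,
                       method = c("lin-up-log-down", "linear"),
                       auc_conversion = 1) {
  method <- match.arg(method)
  times <- profile$times
  conc <- profile$conc
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (sum(conc > 0) < 3) stop("need at least 3 positive concentrations")
  cmax <- max(conc)
  tmax <- times[which.max(conc)]
  auc_last <- .auc_trapezoid(times, conc, method)
  lz <- .fit_lambda_z(times, conc)
  c_last <- utils::tail(conc[conc > 0], 1)
  auc_inf <- auc_last + c_last / lz$lambda

  steady <- isTRUE(profile$steady_state)
  auc_tau <- if (steady && !is.null(profile$tau)) {
    interval_auc(profile, utils::tail(profile$dose_times, 1),
                 utils::tail(profile$dose_times, 1) + profile$tau)
  } else NA_real_
  cl <- if (identical(route, "oral")) {
    if (is.finite(auc_tau) && !is.null(dose_mg)) {
      dose_mg / auc_tau * auc_conversion
    } else NA_real_
  } else if (!is.null(dose_mg)) {
    dose_mg / auc_inf * auc_conversion
  } else NA_real_

  structure(list(cmax = cmax, tmax = tmax, auc_last = auc_last,
                 auc_inf = auc_inf, auc_tau = auc_tau, cl = cl,
                 lambda_z = lz$lambda, n_lambda_points = lz$n,
                 units = profile$units),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> Cmax %.4g @ %.3g h | AUC_last %.4g | AUC_inf %.4g",
              x$cmax, x$tmax, x$auc_last, x$auc_inf))
  if (is.finite(x$auc_tau)) cat(sprintf(" | AUC_tau %.4g", x$auc_tau))
  if (is.finite(x$cl)) cat(sprintf(" | CL %.4g L/h", x$cl))
  cat(sprintf(" | lambda_z %.4g 1/h (%d pts)\n", x$lambda_z, x$n_lambda_points))
  invisible(x)
}

#' Exposure change between two PK parameter sets
#'
#' Ratios (b over a) and percent change `100 * (1 - b/a)` for Cmax and AUC
#' (and CL when present in both), e.g. pregnant over non-pregnant exposure.
#'
#' @param pk_a,pk_b `pk_parameters` objects (or named lists with `cmax`,
#'   `auc`/`auc_inf` and optionally `cl`) computed on the same drug and
#'   regimen.
#' @return Data frame with columns `parameter`, `a`, `b`, `ratio`,
#'   `pct_change`.
#' @export
exposure_change <- function(pk_a, pk_b) {
  pick <- function(pk, what) {
    v <- switch(what,
                cmax = pk$cmax,
                auc = if (!is.null(pk$auc) && is.finite(pk$auc)) pk$auc
                      else if (!is.null(pk$auc_tau) && is.finite(pk$auc_tau)) pk$auc_tau
                      else pk$auc_inf,
                cl = pk$cl)
    if (is.null(v)) NA_real_ else v
  }
  params <- c("cmax", "auc", "cl")
  rows <- lapply(params, function(p) {
    a <- pick(pk_a, p); b <- pick(pk_b, p)
    if (!is.finite(a) || !is.finite(b)) return(NULL)
    if (a == 0) stop("zero denominator in exposure_change for ", p)
    data.frame(parameter = p, a = a, b = b, ratio = b / a,
               pct_change = 100 * (1 - b / a))
  })
  do.call(rbind, rows)
}
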