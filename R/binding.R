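#' Two-protein plasma binding model
#'
#' Linear (non-saturable) binding to albumin and alpha-1-acid glycoprotein
#' (AGP). The model is parameterised by the fraction unbound at reference
#' physiology, `fu_ref`, and two dimensionless bound-load terms (association
#' constant times reference protein concentration) that partition the bound
#' drug between the two proteins. At reference the loads satisfy
#' `load_albumin + load_agp = (1 - fu_ref) / fu_ref`.
#'
#' @param fu_ref Fraction unbound at reference physiology, in (0, 1].
#' @param load_albumin,load_agp Non-negative bound-load terms at reference.
#' @return An object of class `binding_model`.
#' @export
#' @examples
#' binding_model(0.05, load_albumin = 19, load_agp = 0)
binding_model <- function(fu_ref, load_albumin, load_agp = 0) {
  if (!is.numeric(fu_ref) || fu_ref <= 0 || fu_ref > 1) {
    stop("fu_ref must lie in (0, 1]")
  }
  if (load_albumin < 0 || load_agp < 0) stop("bound loads must be >= 0")
  if (abs(load_albumin + load_agp - (1 - fu_ref) / fu_ref) > 1e-9) {
    stop("load_albumin + load_agp must equal (1 - fu_ref)/fu_ref")
  }
  structure(list(fu_ref = fu_ref, load_albumin = load_albumin,
                 load_agp = load_agp),
            class = "binding_model")
}

#' Fraction unbound at scaled binding-protein levels
#'
#' `fu = 1 / (1 + load_albumin * albumin_scalar + load_agp * agp_scalar)`.
#' With both scalers at 1 this returns `fu_ref`; fu decreases strictly in each
#' protein level.
#'
#' @param binding A [binding_model()].
#' @param albumin_scalar,agp_scalar Protein concentrations relative to
#'   reference; strictly positive.
#' @return Fraction unbound in (0, 1].
#' @export
#' @examples
#' b <- binding_model(0.05, 19, 0)
#' fu_at(b, 0.85, 1) # ~0.0583, a 17% increase
fu_at <- function(binding, albumin_scalar = 1, agp_scalar = 1) {
  stopifnot(inherits(binding, "binding_model"))
  if (albumin_scalar <= 0 || agp_scalar <= 0) {
    stop("binding-protein scalers must be strictly positive")
  }
  1 / (1 + binding$load_albumin * albumin_scalar + binding$load_agp * agp_scalar)
}

#' Solve the albumin/AGP bound-load partition from two fu observations
#'
#' Given the fraction unbound at reference physiology and at one alternative
#' physiology (known protein scalers), solves the 2x2 linear system
#' `{La + Lg = (1 - fu_ref)/fu_ref; La*salb + Lg*sagp = (1 - fu_alt)/fu_alt}`
#' for the per-protein bound loads. Used to calibrate a two-protein model when
#' only total fu values are reported.
#'
#' @param fu_ref,fu_alt Fractions unbound at reference and at the alternative
#'   physiology, both in (0, 1).
#' @param albumin_scalar,agp_scalar Protein scalers of the alternative
#'   physiology; must not both equal 1.
#' @return Named numeric vector `c(load_albumin, load_agp)`.
#' @export
#' @examples
#' solve_partition(0.07, 0.06, 0.85, 2.0) # ~c(9.48, 3.80)
solve_partition <- function(fu_ref, fu_alt, albumin_scalar, agp_scalar) {
  if (fu_ref <= 0 || fu_ref >= 1 || fu_alt <= 0 || fu_alt >= 1) {
    stop("fu values must lie in (0, 1)")
  }
  if (albumin_scalar <= 0 || agp_scalar <= 0) {
    stop("scalers must be strictly positive")
  }
  if (albumin_scalar == 1 && agp_scalar == 1) {
    stop("alternative physiology must differ from reference")
  }
  a <- matrix(c(1, 1, albumin_scalar, agp_scalar), nrow = 2, byrow = TRUE)
  b <- c((1 - fu_ref) / fu_ref, (1 - fu_alt) / fu_alt)
  if (abs(det(a)) < 1e-12) {
    stop("singular partition system: albumin and AGP scalers are equal, ",
         "the two fu values do not identify the split")
  }
  loads <- solve(a, b)
  if (any(loads < -1e-9)) {
    stop(sprintf(paste0(
      "no non-negative bound-load partition reproduces fu_ref = %g and ",
      "fu_alt = %g at scalers (%g, %g); solution was (%.4g, %.4g)"),
      fu_ref, fu_alt, albumin_scalar, agp_scalar, loads[1], loads[2]))
  }
  loads <- pmax(loads, 0)
  c(load_albumin = loads[1], load_agp = loads[2])
}
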