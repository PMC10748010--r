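# Independent oracles, deliberately built on different machinery than the
# package (matrix exponentials via eigendecomposition instead of lsoda;
# Riemann sums instead of trapezoids; grid search instead of linear solves).

# Closed-form two-compartment concentration under a single zero-order
# infusion: x' = A x + b with constant b during the infusion.
oracle_infusion_2cpt <- function(cl, v1, v2, q, dose, dur, times) {
  A <- matrix(c(-(cl + q) / v1, q / v2,
                q / v1, -q / v2), 2, 2, byrow = TRUE)
  e <- eigen(A)
  V <- e$vectors
  Vi <- solve(V)
  lam <- e$values
  prop <- function(x0, b, t) {
    xp <- if (all(b == 0)) c(0, 0) else -solve(A, b)
    Re(V %*% (exp(lam * t) * (Vi %*% (x0 - xp))) + xp)
  }
  rate <- dose / dur
  vapply(times, function(t) {
    x <- if (t <= dur) {
      prop(c(0, 0), c(rate, 0), t)
    } else {
      prop(prop(c(0, 0), c(rate, 0), dur), c(0, 0), t - dur)
    }
    x[1] / v1
  }, numeric(1))
}

# Closed-form depot + two-compartment solution for a single oral dose.
oracle_oral_2cpt <- function(cl, v1, v2, q, ka, f_dose, times) {
  A <- matrix(c(-ka, 0, 0,
                ka, -(cl + q) / v1, q / v2,
                0, q / v1, -q / v2), 3, 3, byrow = TRUE)
  e <- eigen(A)
  V <- e$vectors
  Vi <- solve(V)
  lam <- e$values
  x0 <- c(f_dose, 0, 0)
  vapply(times, function(t) {
    Re(V %*% (exp(lam * t) * (Vi %*% x0)))[2] / v1
  }, numeric(1))
}

# Riemann midpoint integral of linearly interpolated data.
oracle_riemann_auc <- function(times, conc, n = 2e5) {
  tt <- seq(min(times), max(times), length.out = n)
  mid <- (tt[-1] + tt[-n]) / 2
  sum(stats::approx(times, conc, xout = mid)$y * diff(tt))
}

# Brute-force grid search for the albumin/AGP bound-load partition.
oracle_partition_grid <- function(fu_ref, fu_alt, salb, sagp, n = 20001) {
  total <- (1 - fu_ref) / fu_ref
  la <- seq(0, total, length.out = n)
  lg <- total - la
  err <- abs(fu_alt - 1 / (1 + la * salb + lg * sagp))
  i <- which.min(err)
  c(load_albumin = la[i], load_agp = lg[i])
}

drug_cache <- new.env(parent = emptyenv())
cached_drug <- function(name) {
  if (is.null(drug_cache[[name]])) drug_cache[[name]] <- load_drug(name)
  drug_cache[[name]]
}
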