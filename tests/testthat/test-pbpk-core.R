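test_that("doses resolve from fixed or body-surface-normalised specifications", {
  iv <- dosing_regimen("iv_infusion", dose_mg_per_m2 = 175, infusion_duration = 3)
  expect_equal(resolve_dose(iv, bsa = 1.86), 325.5)
  expect_equal(resolve_dose(dosing_regimen("iv_infusion", dose_mg_per_m2 = 100,
                                           infusion_duration = 1), 1.82), 182)
  oral <- dosing_regimen("oral", dose_mg = 100, tau = 12, n_doses = 4)
  expect_equal(resolve_dose(oral, bsa = 2.4), 100)
  expect_error(dosing_regimen("iv_infusion", dose_mg = 10, dose_mg_per_m2 = 10,
                              infusion_duration = 1), "exactly one")
  expect_error(dosing_regimen("iv_infusion", dose_mg = 10), "infusion_duration")
  expect_error(dosing_regimen("oral", dose_mg = 10, n_doses = 3), "tau")
})

test_that("numerical infusion profiles match the closed-form solution", {
  model <- disposition_model(v1 = 33.28, v2 = 100, q_inter = 8, cl = 18.6)
  reg <- dosing_regimen("iv_infusion", dose_mg = 325.5, infusion_duration = 3)
  prof <- simulate_profile(model, reg, bsa = 1.86, dt = 0.072, t_end = 72)
  exact <- oracle_infusion_2cpt(18.6, 33.28, 100, 8, 325.5, 3, prof$times)
  i <- exact > max(exact) * 1e-6
  expect_lt(max(abs(prof$conc[i] / exact[i] - 1)), 0.005)
})

test_that("numerical oral profiles match the closed-form solution", {
  model <- disposition_model(v1 = 11.35, v2 = 10, q_inter = 5, cl = 22,
                             ka = 2, f_oral = 0.19)
  reg <- dosing_regimen("oral", dose_mg = 100, tau = 12, n_doses = 1)
  prof <- simulate_profile(model, reg, bsa = 1.8, dt = 0.05, t_end = 12)
  exact <- oracle_oral_2cpt(22, 11.35, 10, 5, 2, 0.19 * 100, prof$times)
  i <- exact > max(exact) * 1e-6
  expect_lt(max(abs(prof$conc[i] / exact[i] - 1)), 0.005)
  # multiple dosing equals superposition of shifted single doses
  reg3 <- dosing_regimen("oral", dose_mg = 100, tau = 12, n_doses = 3)
  prof3 <- simulate_profile(model, reg3, bsa = 1.8, dt = 0.05, t_end = 36)
  super <- exact_sum <- numeric(length(prof3$times))
  for (td in c(0, 12, 24)) {
    tt <- pmax(prof3$times - td, 0)
    contrib <- oracle_oral_2cpt(22, 11.35, 10, 5, 2, 0.19 * 100, tt)
    contrib[prof3$times < td] <- 0
    super <- super + contrib
  }
  i <- super > max(super) * 1e-6
  expect_lt(max(abs(prof3$conc[i] / super[i] - 1)), 0.005)
})

test_that("one-compartment limit is mono-exponential after the infusion", {
  # negligible peripheral compartment: post-infusion decline at k = cl/v1
  model <- disposition_model(v1 = 50, v2 = 1e-4, q_inter = 1e-4, cl = 10)
  reg <- dosing_regimen("iv_infusion", dose_mg = 100, infusion_duration = 0.5)
  prof <- simulate_profile(model, reg, bsa = 1.8, dt = 0.05, t_end = 24)
  post <- prof$times >= 0.5
  k <- 10 / 50
  expected <- (100 / 0.5) / 10 * (1 - exp(-k * 0.5)) * exp(-k * (prof$times[post] - 0.5))
  expect_equal(prof$conc[post], expected, tolerance = 0.002)
  # concentration peaks at end of infusion
  expect_equal(prof$times[which.max(prof$conc)], 0.5)
})

test_that("profiles are dose-proportional and mass-balanced", {
  model <- disposition_model(v1 = 22.42, v2 = 300, q_inter = 20, cl = 52)
  reg1 <- dosing_regimen("iv_infusion", dose_mg = 100, infusion_duration = 1)
  reg2 <- dosing_regimen("iv_infusion", dose_mg = 200, infusion_duration = 1)
  p1 <- simulate_profile(model, reg1, 1.8, dt = 0.1, t_end = 96)
  p2 <- simulate_profile(model, reg2, 1.8, dt = 0.1, t_end = 96)
  expect_equal(p2$conc, 2 * p1$conc, tolerance = 1e-6)
  # AUC_inf x CL = Dose within 1%
  pk <- compute_pk(p1, dose_mg = 100, route = "iv_infusion")
  expect_equal(pk$auc_inf * 52 / 100, 1, tolerance = 0.01)
})

test_that("oral steady-state interval AUC obeys F x Dose / CL", {
  model <- disposition_model(v1 = 11.35, v2 = 10, q_inter = 5, cl = 22,
                             ka = 2, f_oral = 0.19)
  reg <- dosing_regimen("oral", dose_mg = 100, tau = 12, n_doses = 16)
  prof <- simulate_profile(model, reg, 1.8, dt = 0.05, t_end = 192)
  win <- steady_state_window(prof, k = 2)
  expect_equal(max(win$times), 24)
  auc_tau <- compute_pk(win, dose_mg = 100, route = "oral")$auc_tau
  expect_equal(auc_tau * 22 / (0.19 * 100), 1, tolerance = 0.01)
})

test_that("steady-state extraction validates convergence and coverage", {
  # ten doses at tau of ~5 half-lives: interval AUC equals single-dose AUC_inf
  model <- disposition_model(v1 = 50, v2 = 1e-4, q_inter = 1e-4, cl = 10,
                             ka = 1, f_oral = 0.5)
  t_half <- log(2) / (10 / 50)
  tau <- 5 * t_half
  reg <- dosing_regimen("oral", dose_mg = 100, tau = tau, n_doses = 10)
  prof <- simulate_profile(model, reg, 1.8, dt = 0.05, t_end = 10 * tau)
  win <- steady_state_window(prof, k = 1)
  single <- simulate_profile(model,
                             dosing_regimen("oral", dose_mg = 100, tau = tau,
                                            n_doses = 1),
                             1.8, dt = 0.05, t_end = 6 * tau)
  auc_inf <- compute_pk(single, dose_mg = 100, route = "iv_infusion")$auc_inf
  expect_equal(oracle_riemann_auc(win$times, win$conc) / auc_inf, 1,
               tolerance = 0.01)

  # a long-half-life drug after 2 doses has not converged
  slow <- disposition_model(v1 = 50, v2 = 1e-4, q_inter = 1e-4, cl = 1,
                            ka = 1, f_oral = 0.5)
  reg3 <- dosing_regimen("oral", dose_mg = 100, tau = 12, n_doses = 3)
  prof3 <- simulate_profile(slow, reg3, 1.8, dt = 0.1, t_end = 36)
  expect_error(steady_state_window(prof3, k = 1), "steady state not reached")
})
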