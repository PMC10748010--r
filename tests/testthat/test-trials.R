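test_that("prediction evaluation applies the two-fold and 25% criteria", {
  r <- evaluate_prediction(list(auc = 11.8), list(auc = 8.7))
  expect_equal(r$ratio, 11.8 / 8.7, tolerance = 1e-9) # 1.36
  expect_true(r$within_twofold)
  expect_false(r$within_25pct)

  same <- evaluate_prediction(list(cmax = 2, auc = 9), list(cmax = 2, auc = 9))
  expect_true(all(same$within_twofold) && all(same$within_25pct))

  doc <- evaluate_prediction(list(auc = 2.8), list(auc = 2.4))
  expect_equal(doc$ratio, 2.8 / 2.4, tolerance = 1e-9) # 1.17
  expect_true(doc$within_twofold && doc$within_25pct)

  expect_error(evaluate_prediction(list(auc = 1), list(auc = 0)), "zero")
})

test_that("virtual trials are seeded, reproducible, and centred on the anchor", {
  aca <- cached_drug("acalabrutinib")
  tr1 <- run_virtual_trial(aca, "cancer", n_trials = 3, n_subjects = 5,
                           seed = 42, dt = 0.2)
  tr2 <- run_virtual_trial(aca, "cancer", n_trials = 3, n_subjects = 5,
                           seed = 42, dt = 0.2)
  expect_identical(tr1$params, tr2$params)
  tr3 <- run_virtual_trial(aca, "cancer", n_trials = 3, n_subjects = 5,
                           seed = 43, dt = 0.2)
  expect_false(identical(tr1$params, tr3$params))
  expect_true(all(tr1$params$p05 <= tr1$params$mean &
                  tr1$params$mean <= tr1$params$p95))

  # zero variability collapses every percentile onto the representative value
  flat <- run_virtual_trial(aca, "cancer", n_trials = 2, n_subjects = 3,
                            seed = 1, dt = 0.2,
                            variability = list(cyp3a4 = 0, cyp2c8 = 0,
                                               albumin = 0, agp = 0),
                            bsa_range = NULL)
  rep_nca <- drug_nca(aca, "cancer", dt = 0.2)
  for (p in c("cmax", "auc")) {
    row <- flat$params[flat$params$parameter == p, ]
    expect_equal(row$p05, row$p95, tolerance = 1e-9)
    expect_equal(row$mean, rep_nca[[p]], tolerance = 1e-6)
  }
})

test_that("trial means stabilise as the number of subjects grows", {
  doc <- cached_drug("docetaxel")
  small <- run_virtual_trial(doc, "cancer", n_trials = 1, n_subjects = 40,
                             seed = 5, dt = 0.25)
  big <- run_virtual_trial(doc, "cancer", n_trials = 1, n_subjects = 400,
                           seed = 5, dt = 0.25)
  m <- function(tr, p) tr$params$mean[tr$params$parameter == p]
  # drift bound ~3 sigma of the small-sample mean (CV ~35% at n = 40)
  expect_lt(abs(m(small, "auc") / m(big, "auc") - 1), 0.17)
  expect_lt(abs(m(small, "cl") / m(big, "cl") - 1), 0.17)
})

test_that("prediction-interval coverage behaves at the extremes", {
  band <- data.frame(time = 0:10, p05 = rep(1, 11), p95 = rep(3, 11))
  expect_equal(pi_coverage(0:10, rep(2, 11), band), 1.0)   # at the centre
  expect_equal(pi_coverage(0:10, rep(5, 11), band), 0.0)   # above the 95th
  expect_error(pi_coverage(c(5, 12), c(2, 2), band), "outside")
})

test_that("representative population comparison equals single-subject ratios", {
  aca <- cached_drug("acalabrutinib")
  cmp <- population_comparison(aca, "pregnancy", "cancer", gw_a = 32)
  n_p <- drug_nca(aca, "pregnancy", gw = 32)
  n_c <- drug_nca(aca, "cancer")
  expect_equal(cmp$ratio[cmp$parameter == "auc"], n_p$auc / n_c$auc,
               tolerance = 1e-9)
  expect_equal(cmp$ratio[cmp$parameter == "cmax"], n_p$cmax / n_c$cmax,
               tolerance = 1e-9)
  same <- population_comparison(aca, "cancer", "cancer")
  expect_equal(same$ratio, c(1, 1), tolerance = 1e-9)
})

test_that("sensitivity analysis respects well-stirred monotonicity", {
  doc <- cached_drug("docetaxel")
  s <- sensitivity_analysis(doc, "cyp3a4", c(0.5, 1, 2))
  expect_true(all(diff(s$cl) > 0))
  expect_true(all(diff(s$auc) < 0))
  expect_equal(s$cl[s$multiplier == 1], doc$elim$cl_ref, tolerance = 1e-9)
  # doubling GFR moves docetaxel clearance by well under 10% (f_renal 0.05)
  g <- sensitivity_analysis(doc, "gfr", c(1, 2))
  expect_lt(abs(g$cl[2] / g$cl[1] - 1), 0.10)
  expect_error(sensitivity_analysis(doc, "lipoprotein", 1), "arg")
})

test_that("the decision workflow selects the published population models", {
  pac <- cached_drug("paclitaxel")
  doc <- cached_drug("docetaxel")
  obs_pac <- list(load_fixture("paclitaxel_vanhasselt"),
                  load_fixture("paclitaxel_janssen"))
  obs_doc <- list(load_fixture("docetaxel_vanhasselt"),
                  load_fixture("docetaxel_janssen"))

  wf_doc <- decision_workflow(doc, obs_doc)
  expect_equal(wf_doc$selected, "pregnancy")
  expect_true(wf_doc$validated)
  expect_true(wf_doc$audit$healthy_vs_cancer$equivalent)

  wf_pac <- decision_workflow(pac, obs_pac)
  expect_equal(wf_pac$selected, "pregnancy_cyp2c8")
  expect_true(wf_pac$validated)
  expect_true(wf_pac$audit$healthy_vs_cancer$equivalent)
  # the default pregnancy model was tried and rejected first
  expect_false(wf_pac$audit$default_pregnancy$pass)

  # observations equal to the default-pregnancy prediction exit at step 2
  n_preg <- drug_nca(doc, "pregnancy", gw = 32)
  wf_self <- decision_workflow(doc, list(auc = n_preg$auc, cl = n_preg$cl))
  expect_equal(wf_self$selected, "pregnancy")

  # the workflow is a pure function: replaying gives the same audit trail
  expect_equal(decision_workflow(pac, obs_pac)$audit$default_pregnancy$comparisons,
               wf_pac$audit$default_pregnancy$comparisons)
})
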