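make_elim <- function(...) elimination_model(...)

test_that("well-stirred inversion recovers intrinsic clearances", {
  # paclitaxel-like split: hepatic CL 16.74 of qh 90
  e <- make_elim(0.40, 0.40, 0.10, 0.10, cl_ref = 18.6)
  ic <- back_calculate(e, qh = 90)
  s_total <- 90 * 16.74 / (90 - 16.74) # hand well-stirred inversion
  expect_equal(ic$fu_clint_cyp3a4, s_total * 4 / 9, tolerance = 1e-9)
  expect_equal(ic$fu_clint_cyp2c8, s_total * 4 / 9, tolerance = 1e-9)
  expect_equal(ic$fu_clint_other, s_total * 1 / 9, tolerance = 1e-9)
  expect_equal(ic$cl_renal_ref, 1.86)

  # all-renal drug: no hepatic intrinsic clearance
  r <- back_calculate(make_elim(0, 0, 0, 1, cl_ref = 5), qh = 90)
  expect_equal(r$fu_clint_cyp3a4 + r$fu_clint_cyp2c8 + r$fu_clint_other, 0)
  expect_equal(r$cl_renal_ref, 5)

  # near flow-limited: 90 * 89 / (90 - 89) = 8010 by hand
  f <- back_calculate(make_elim(1, 0, 0, 0, cl_ref = 89), qh = 90)
  expect_equal(f$fu_clint_cyp3a4, 8010, tolerance = 1e-9)

  expect_error(back_calculate(make_elim(1, 0, 0, 0, cl_ref = 95), qh = 90),
               "extraction ratio")
  expect_error(make_elim(0.5, 0.3, 0.1, 0.2, cl_ref = 10), "sum to 1")
})

test_that("clearance prediction is an identity at the reference subject", {
  ref <- reference_physiology()
  b <- binding_model(0.05, 19, 0)
  e <- make_elim(0.40, 0.40, 0.10, 0.10, cl_ref = 18.6)
  ic <- back_calculate(e, 90)
  sub <- apply_scalers(ref, make_population("healthy"))
  p <- predict_cl(e, ic, b, sub, sub, ref, qh = 90)
  expect_equal(p$cl, 18.6, tolerance = 1e-9)
  expect_equal(p$fu, 0.05)
})

test_that("pregnancy translation reproduces the published clearance shifts", {
  pac <- cached_drug("paclitaxel")
  # CYP2C8-modified pregnancy model at 32 GW: published mean CL 33.2 L/h
  p_mod <- drug_predict(pac, "pregnancy_cyp2c8", gw = 32)
  expect_equal(p_mod$cl, 37.92, tolerance = 0.005)    # hand well-stirred value
  expect_lt(abs(p_mod$cl / 33.2 - 1), 0.25)
  expect_equal(p_mod$fu, 1 / (1 + 19 * 0.75), tolerance = 1e-9) # fu 0.0656

  doc <- cached_drug("docetaxel")
  # default pregnancy model at 32 GW: published mean CL 65 L/h
  p_doc <- drug_predict(doc, "pregnancy", gw = 32)
  expect_equal(p_doc$cl, 71.65, tolerance = 0.005)
  expect_lt(abs(p_doc$cl / 65 - 1), 0.25)
})

test_that("predicted clearance is monotone in abundance scalers and fu", {
  ref <- reference_physiology()
  b <- binding_model(0.05, 19, 0)
  e <- make_elim(0.40, 0.40, 0.10, 0.10, cl_ref = 18.6)
  ic <- back_calculate(e, 90)
  base <- apply_scalers(ref, make_population("healthy"))
  cl_at <- function(mod) {
    s <- make_population("healthy")
    for (k in names(mod)) s[[k]] <- mod[[k]]
    predict_cl(e, ic, b, apply_scalers(ref, s), base, ref, 90)$cl
  }
  grid <- c(0.5, 1, 1.5, 2, 3)
  expect_true(all(diff(vapply(grid, function(m)
    cl_at(list(cyp3a4_scalar = m)), numeric(1))) > 0))
  expect_true(all(diff(vapply(grid, function(m)
    cl_at(list(cyp2c8_scalar = m)), numeric(1))) > 0))
  # lower albumin -> higher fu -> higher clearance
  expect_true(all(diff(vapply(rev(grid) / 2, function(m)
    cl_at(list(albumin_scalar = m)), numeric(1))) > 0))
  # hepatic clearance never exceeds blood flow, however induced the enzymes
  s_huge <- make_population("healthy")
  s_huge$cyp3a4_scalar <- 500
  p_huge <- predict_cl(e, ic, b, apply_scalers(ref, s_huge), base, ref, 90)
  expect_lt(p_huge$cl_hepatic, 90)
})

test_that("low-extraction clearance ratios reduce to fu x abundance scaling", {
  ref <- reference_physiology()
  b <- binding_model(0.05, 19, 0)
  e <- make_elim(0.8, 0, 0.2, 0, cl_ref = 0.9) # S << qh
  ic <- back_calculate(e, 90)
  base <- apply_scalers(ref, make_population("healthy"))
  target <- apply_scalers(ref, make_population("pregnancy", 32))
  p <- predict_cl(e, ic, b, target, base, ref, 90)
  fu_ratio <- p$fu / 0.05
  closed_form <- 0.9 * fu_ratio * (0.8 * 2.0 + 0.2)
  expect_equal(p$cl / closed_form, 1, tolerance = 0.02)
})

test_that("oral availability follows the well-stirred first-pass limits", {
  expect_equal(oral_availability(0, 90, 0.25), 0.25)        # S -> 0
  expect_equal(oral_availability(90, 90, 0.25), 0.125)      # S = qh
  expect_error(oral_availability(10, 90, 1.2), "fabs_fg")
  # consistency: oral steady-state AUC equals fabs_fg * Dose / S
  aca <- cached_drug("acalabrutinib")
  pred <- drug_predict(aca, "cancer")
  auc_tau_mg_h_l <- aca$fabs_fg * 100 / pred$s
  expect_equal(auc_tau_mg_h_l * 1000 * 2, 1719, tolerance = 0.001)
})
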