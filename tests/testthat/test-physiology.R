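test_that("population scalers reproduce the implemented physiological changes", {
  h <- make_population("healthy")
  expect_equal(unlist(h[c("albumin_scalar", "agp_scalar", "cyp3a4_scalar",
                          "cyp2c8_scalar", "gfr_scalar")]),
               c(albumin_scalar = 1, agp_scalar = 1, cyp3a4_scalar = 1,
                 cyp2c8_scalar = 1, gfr_scalar = 1))

  ca <- make_population("cancer")
  expect_equal(ca$albumin_scalar, 0.85)
  expect_equal(ca$agp_scalar, 2.0)
  expect_equal(ca$cyp3a4_scalar, 1.0)
  expect_equal(ca$cyp2c8_scalar, 1.0)
  expect_equal(ca$gfr_scalar, 0.65) # midpoint of the 30-40% decrease

  pm <- make_population("pregnancy_cyp2c8", gestational_week = 32)
  expect_equal(pm$albumin_scalar, 0.75)
  expect_equal(pm$agp_scalar, 0.70)
  expect_equal(pm$cyp3a4_scalar, 2.0)
  expect_equal(pm$cyp2c8_scalar, 2.5)
  expect_equal(pm$gfr_scalar, 1.25)

  pd <- make_population("pregnancy", gestational_week = 32)
  expect_equal(pd$cyp2c8_scalar, 1.0)
})

test_that("population construction enforces gestational-week rules", {
  expect_error(make_population("cancer", gestational_week = 32), "gestational")
  expect_error(make_population("pregnancy"), "gestational_week")
  expect_error(make_population("pregnancy", gestational_week = 50), "42")
  expect_error(make_population("pregnancy", gestational_week = 0), "42")
})

test_that("gestational-week profiles interpolate linearly through the anchors", {
  expect_equal(gw_profile("cyp3a4", 0), 1.0)
  expect_equal(gw_profile("cyp3a4", 32), 2.0)
  expect_equal(gw_profile("cyp3a4", 16), 1.5) # midpoint of (0,1)-(32,2)
  expect_equal(gw_profile("cyp3a4", 40), 2.3) # term
  expect_equal(gw_profile("albumin", 8), 1 - 0.25 / 4)
  expect_equal(gw_profile("gfr", 32), 1.25)
  # CYP2C8 is flat throughout pregnancy at its population value
  expect_equal(gw_profile("cyp2c8", 10), 1.0)
  expect_equal(gw_profile("cyp2c8", 10, cyp2c8_induction = TRUE), 2.5)
  expect_equal(gw_profile("cyp2c8", 40, cyp2c8_induction = TRUE), 2.5)
  expect_error(gw_profile("cyp9z9", 10), "unknown parameter")

  # piecewise linearity within segments, continuity at the 32-GW anchor
  expect_equal(gw_profile("cyp3a4", 36), (2.0 + 2.3) / 2)
  expect_equal(gw_profile("agp", 24), 1 + (0.70 - 1) * 24 / 32)
  expect_equal(gw_profile("cyp3a4", 32 - 1e-9), 2.0, tolerance = 1e-7)
  expect_equal(gw_profile("cyp3a4", 32 + 1e-9), 2.0, tolerance = 1e-7)
})

test_that("applying scalers realizes the representative subject", {
  ref <- reference_physiology()
  h <- apply_scalers(ref, make_population("healthy"))
  expect_equal(h$albumin, ref$albumin)
  expect_equal(h$cyp2c8_abundance, ref$cyp2c8_abundance)
  expect_equal(h$gfr, ref$gfr)

  ca <- apply_scalers(ref, make_population("cancer"))
  expect_equal(ca$albumin, 45 * 0.85) # 38.25 g/L
  pm <- apply_scalers(ref, make_population("pregnancy_cyp2c8", 32))
  expect_equal(pm$cyp2c8_abundance, 60) # 24 pmol/mg x 2.5
})

test_that("subject sampling is seeded, reproducible, and mean-preserving", {
  ref <- reference_physiology()
  sc <- make_population("cancer")

  zero <- sample_subjects(ref, sc, n = 3,
                          variability = list(cyp3a4 = 0, albumin = 0),
                          seed = 1)
  rep_sub <- apply_scalers(ref, sc)
  for (s in zero) {
    expect_equal(s$cyp3a4_scalar, rep_sub$cyp3a4_scalar)
    expect_equal(s$albumin, rep_sub$albumin)
  }

  a <- sample_subjects(ref, sc, n = 10, seed = 7)
  b <- sample_subjects(ref, sc, n = 10, seed = 7)
  expect_identical(a, b)
  c2 <- sample_subjects(ref, sc, n = 10, seed = 8)
  expect_false(identical(a, c2))

  big <- sample_subjects(ref, sc, n = 400,
                         variability = list(cyp3a4 = 0.3), seed = 7)
  gm <- exp(mean(log(vapply(big, `[[`, numeric(1), "cyp3a4_scalar"))))
  expect_lt(abs(gm / rep_sub$cyp3a4_scalar - 1), 0.05)

  expect_error(sample_subjects(ref, sc, n = 2,
                               variability = list(cyp3a4 = -0.1), seed = 1),
               ">= 0")
})
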