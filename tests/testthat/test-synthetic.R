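test_that("skin model: identity, monotonicity in melanin, hemoglobin bands", {
  # no chromophores: flat baseline
  flat <- skin_reflectance(skin_phenotype(0, 0, 0.6), hs_wl33)
  expect_equal(flat$value, rep(0.6, 33))
  # monotone: more melanin, less reflectance (parameter sweep)
  mel <- seq(0.1, 3, length.out = 12)
  means <- sapply(mel, function(m) {
    mean(skin_reflectance(skin_phenotype(m, 0.5, 0.6, g1_melanin_max = 10), hs_wl33)$value)
  })
  expect_true(all(diff(means) < 0))
  # hemoglobin bands: local minima at the grid points nearest 542 and 577 nm
  s <- skin_reflectance(skin_phenotype(0, 1, 0.6), hs_wl33)
  v <- s$value
  minima <- hs_wl33[which(diff(sign(diff(v))) == 2) + 1]
  expect_true(540 %in% minima)
  expect_true(580 %in% minima)
  expect_error(skin_reflectance(skin_phenotype(NaN, 0, 0.5)), "finite")
})

test_that("phenotype invariants are enforced", {
  expect_error(skin_phenotype(-0.1, 0, 0.5), ">= 0")
  expect_error(skin_phenotype(0.5, 0.5, 0), "baseline")
  expect_error(skin_phenotype(0.5, 0.5, 1.2), "baseline")
  # a G2 face must exceed the configured G1 melanin upper bound
  expect_error(skin_phenotype(0.4, 0.5, 0.6, group = "G2"), "G1 upper bound")
  expect_s3_class(skin_phenotype(2.5, 0.5, 0.6, group = "G2"), "skin_phenotype")
})

test_that("rendering honors the 85% full-scale exposure rule and is deterministic", {
  sc <- tiny_scene(seed = 12)
  raw <- render_face_cube(sc, noise = FALSE)
  per_band_max <- apply(raw$values, 3, max)
  expect_true(all(per_band_max == round(0.85 * 4095))) # 3481
  raw2 <- render_face_cube(sc, noise = FALSE)
  expect_identical(raw$values, raw2$values)
  # with noise: still bit-identical for the same seed
  n1 <- render_face_cube(sc); n2 <- render_face_cube(sc)
  expect_identical(n1$values, n2$values)
  # 12-bit range
  expect_gte(min(n1$values), 0)
  expect_lte(max(n1$values), 4095)
})

test_that("scene invariants: positive gain with mean one, flat reference patch, truth in [0,1]", {
  sc <- tiny_scene(seed = 9)
  expect_true(all(sc$gain_field > 0))
  expect_equal(mean(sc$gain_field), 1, tolerance = 1e-12)
  ref_vals <- sc$truth$values[sc$reference$rows, sc$reference$cols, ]
  expect_true(all(ref_vals == 0.431)) # spectrally flat at every band
  expect_true(all(sc$truth$values >= 0 & sc$truth$values <= 1))
})

test_that("device readings average ground truth over the aperture", {
  sc <- symmetric_scene() # spatially uniform skin
  truth_tsr <- skin_reflectance(sc$phenotype, seq(380, 780, 4))
  tsr <- simulate_device_readings(sc, "TSR", 1)
  expect_equal(tsr$value, truth_tsr$value, tolerance = 1e-12)
  truth_spm <- skin_reflectance(sc$phenotype, seq(400, 700, 10))
  spm <- simulate_device_readings(sc, "SPM", 13)
  expect_equal(spm$value, truth_spm$value, tolerance = 1e-12)
  # SPM point inside the TSR area agrees with it after regridding (up to the
  # 4 nm -> 10 nm linear-interpolation error of the steep blue edge)
  tsr_common <- regrid_spectrum(tsr, seq(400, 700, 10))
  expect_lt(max(abs(spm$value - tsr_common$value)), 5e-3)
  # multiplicative bias is linear
  biased <- simulate_device_readings(sc, "SPM", 13, bias = 1.1)
  expect_equal(biased$value, 1.1 * spm$value, tolerance = 1e-12)
  expect_error(simulate_device_readings(sc, "TSR", 10), "Unknown")
  expect_error(simulate_device_readings(sc, "SPM", 40), "Unknown")
})

test_that("make_cohort reproduces the 25/4 group split and is deterministic", {
  coh <- make_cohort(29, 4 / 29, seed = 1, dim = c(24, 32))
  groups <- vapply(coh, function(s) s$group, character(1))
  expect_equal(sum(groups == "G1"), 25)
  expect_equal(sum(groups == "G2"), 4)
  all_g1 <- make_cohort(3, 0, seed = 2, dim = c(24, 32))
  expect_true(all(vapply(all_g1, function(s) s$group, character(1)) == "G1"))
  coh2 <- make_cohort(29, 4 / 29, seed = 1, dim = c(24, 32))
  expect_equal(vapply(coh, function(s) s$phenotype$melanin, numeric(1)),
               vapply(coh2, function(s) s$phenotype$melanin, numeric(1)))
  # every G2 melanin above every G1 melanin (group invariant)
  mel <- vapply(coh, function(s) s$phenotype$melanin, numeric(1))
  expect_gt(min(mel[groups == "G2"]), max(mel[groups == "G1"]))
})

test_that("pixelwise L* decreases strictly with melanin, all else fixed", {
  mel <- c(0.1, 0.4, 1, 1.8, 2.6, 3.4)
  L <- sapply(mel, function(m) {
    lab_from_spectrum(skin_reflectance(skin_phenotype(m, 1.2, 0.64, g1_melanin_max = 10),
                                       hs_wl33))["L"]
  })
  expect_true(all(diff(L) < 0))
})
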