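test_that("correct_raw subtracts dark and stray and logs clamping", {
  vals <- array(100, c(3, 3, 2))
  cube <- spectral_cube(vals, c(500, 510), "raw_counts")
  expect_equal(correct_raw(cube)$values, vals) # identity with zero corrections
  out <- correct_raw(cube, dark = 10, stray = 5)
  expect_true(all(out$values == 85))
  low <- spectral_cube(array(3, c(2, 2, 1)), 500, "raw_counts")
  expect_message(clamped <- correct_raw(low, dark = 10), "clamped")
  expect_true(all(clamped$values == 0))
  expect_equal(clamped$metadata$n_clamped, 4)
  expect_error(correct_raw(cube, dark = -1), "nonnegative")
})

test_that("compute_radiance applies the gray-reference ratio", {
  vals <- array(100, c(4, 4, 1))
  vals[1:2, 1:2, 1] <- 200 # reference patch
  cube <- spectral_cube(vals, 550, "raw_counts")
  ref <- reference_region(1:2, 1:2, spectrum(550, 2.0, "radiance"))
  rad <- compute_radiance(cube, ref)
  expect_equal(rad$values[3, 3, 1], 100 * 2.0 / 200) # = 1.0
  expect_equal(rad$values[1, 1, 1], 2.0) # reference pixels recover their radiance
  zero <- spectral_cube(array(0, c(4, 4, 1)), 550, "raw_counts")
  expect_error(compute_radiance(zero, ref), "zero at band")
})

test_that("radiance and reflectance agree with per-pixel loop oracles on small cubes", {
  withr::with_seed(33, {
    nr <- 6; nc <- 8; nb <- 5
    wl <- seq(500, 540, 10)
    counts <- array(runif(nr * nc * nb, 10, 3000), c(nr, nc, nb))
    n7 <- spectrum(wl, runif(nb, 0.5, 2), "radiance")
    ref <- reference_region(1:2, 1:3, n7)
    rad <- compute_radiance(spectral_cube(counts, wl, "raw_counts"), ref)
    S <- spectrum(wl, runif(nb, 0.5, 2), "illuminant_power")
    gain <- matrix(runif(nr * nc, 0.8, 1.2), nr, nc)
    refl <- suppressWarnings(suppressMessages(compute_reflectance(rad, S, gain)))
    # independent elementwise loop
    for (b in seq_len(nb)) {
      ref_mean <- mean(counts[1:2, 1:3, b])
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        beta <- counts[i, j, b] * n7$value[b] / ref_mean
        expect_equal(rad$values[i, j, b], beta, tolerance = 1e-12)
        expect_equal(refl$values[i, j, b], beta / (S$value[b] * gain[i, j]),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("scaling all counts leaves reflectance unchanged (reference cancels)", {
  sc <- tiny_scene(seed = 3, read_sigma = 0, shot_scale = 0)
  raw <- render_face_cube(sc, noise = FALSE)
  ref <- scene_reference_region(sc)
  r1 <- compute_reflectance(compute_radiance(raw, ref),
                            sc$illuminant, sc$gain_field)
  scaled <- spectral_cube(raw$values * 3.7, raw$wavelengths, "raw_counts")
  r2 <- compute_reflectance(compute_radiance(scaled, ref),
                            sc$illuminant, sc$gain_field)
  expect_equal(r2$values, r1$values, tolerance = 1e-12)
})

test_that("estimate_illuminant_field recovers uniform and split-field structure", {
  wl <- seq(500, 540, 10)
  base <- runif(5, 0.5, 2)
  uni <- spectral_cube(array(rep(base, each = 36), c(6, 6, 5)), wl, "radiance")
  f <- estimate_illuminant_field(uni)
  expect_equal(f$gain_field, matrix(1, 6, 6), tolerance = 1e-12)
  expect_equal(f$illuminant_spd$value, base, tolerance = 1e-12)
  # left half x0.9, right half x1.1
  gain_true <- matrix(rep(c(0.9, 1.1), each = 18), 6, 6)
  vals <- array(0, c(6, 6, 5))
  for (b in 1:5) vals[, , b] <- gain_true * base[b]
  f2 <- estimate_illuminant_field(spectral_cube(vals, wl, "radiance"))
  expect_equal(f2$gain_field, gain_true / mean(gain_true), tolerance = 1e-12)
})

test_that("the rendered gain field is recovered from a flat white acquisition", {
  sc <- tiny_scene(seed = 17, dim = c(48, 64), read_sigma = 0, shot_scale = 0)
  flat <- counts_to_radiance(render_flat_cube(sc, noise = FALSE))
  f <- estimate_illuminant_field(flat)
  expect_lt(max(abs(f$gain_field - sc$gain_field)), 2e-3) # quantization only
  expect_lt(max(abs(f$illuminant_spd$value / sc$illuminant$value - 1)), 1e-3)
})

test_that("noise-free synthetic round trip recovers truth within quantization", {
  sc <- tiny_scene(seed = 5, dim = c(64, 96), read_sigma = 0, shot_scale = 0)
  refl <- recover_reflectance(sc, noise = FALSE, illuminant_field = "truth")
  expect_lt(max(abs(refl$values - sc$truth$values)), 2e-4)
  # full estimated-field path stays within a few quantization steps
  refl2 <- recover_reflectance(sc, noise = FALSE)
  expect_lt(max(abs(refl2$values - sc$truth$values)), 1e-3)
})

test_that("the recovered gray reference is flat and matches its known reflectance", {
  sc <- tiny_scene(seed = 23, read_sigma = 0, shot_scale = 0)
  refl <- recover_reflectance(sc, noise = FALSE)
  patch <- refl$values[sc$reference$rows, sc$reference$cols, ]
  per_band <- apply(patch, 3, mean)
  expect_equal(mean(per_band), 0.431, tolerance = 1e-3)
  expect_lt(sd(per_band) / mean(per_band), 0.01) # spectrally flat: CV < 1%
})

test_that("reflectance_from_ratio implements the white-diffuser ratio", {
  wl <- seq(400, 700, 10)
  white <- spectrum(wl, runif(31, 0.5, 2), "radiance")
  expect_equal(reflectance_from_ratio(white, white)$value, rep(1, 31))
  skin <- spectrum(wl, 0.3 * white$value, "radiance")
  expect_equal(reflectance_from_ratio(skin, white)$value, rep(0.3, 31),
               tolerance = 1e-12)
  expect_error(reflectance_from_ratio(spectrum(wl + 2, white$value, "radiance"),
                                      white), "grid")
  expect_error(reflectance_from_ratio(skin, spectrum(wl, rep(0, 31), "radiance")),
               "positive")
})

test_that("reflectance above 1.5 is flagged but preserved", {
  wl <- c(500, 510)
  rad <- spectral_cube(array(c(2, 1, 1, 1, 2, 1, 1, 1), c(2, 2, 2)), wl, "radiance")
  S <- spectrum(wl, c(1, 1), "illuminant_power")
  expect_message(refl <- suppressWarnings(compute_reflectance(rad, S)), "flagged")
  expect_equal(max(refl$values), 2)
  expect_equal(refl$metadata$n_above_1p5, 2)
})
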