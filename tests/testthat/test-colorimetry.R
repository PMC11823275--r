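flat33 <- function(x) spectrum(hs_wl33, rep(x, 33))

test_that("tristimulus integration is normalized and linear in reflectance", {
  expect_equal(unname(reflectance_to_xyz(flat33(1))["Y"]), 100)
  expect_equal(as.numeric(reflectance_to_xyz(flat33(0))), c(0, 0, 0))
  expect_equal(unname(reflectance_to_xyz(flat33(0.431))["Y"]), 43.1)
  # linearity: XYZ of a x R1 + b x R2
  withr::with_seed(8, {
    r1 <- runif(33); r2 <- runif(33)
    x1 <- reflectance_to_xyz(spectrum(hs_wl33, r1))
    x2 <- reflectance_to_xyz(spectrum(hs_wl33, r2))
    x12 <- reflectance_to_xyz(spectrum(hs_wl33, 0.3 * r1 + 0.7 * r2))
    expect_equal(unname(x12), unname(0.3 * x1 + 0.7 * x2), tolerance = 1e-12)
  })
})

test_that("CIELAB conversion matches the closed-form branches", {
  white <- c(95, 100, 105)
  expect_equal(unname(xyz_to_lab(white, white)), c(100, 0, 0))
  # gray at 0.431 of the white: cube-root branch
  lab <- xyz_to_lab(0.431 * white, white)
  expect_equal(unname(lab["L"]), 116 * 0.431^(1 / 3) - 16, tolerance = 1e-12)
  expect_equal(unname(lab[c("a", "b")]), c(0, 0), tolerance = 1e-12)
  # deep shadow: linear branch, L* = (116 * 841/108) (Y/Yn) = 903.3 (Y/Yn)
  lab_lo <- xyz_to_lab(0.001 * white, white)
  expect_equal(unname(lab_lo["L"]), 116 * (841 / 108) * 0.001, tolerance = 1e-12)
  expect_error(xyz_to_lab(c(-1, 50, 50), white), "Negative")
})

test_that("delta E examples and edge cases evaluate correctly", {
  g1 <- c(61.8, 12.9, 17.5); g2 <- c(39.4, 12.6, 16.4)
  expect_equal(delta_e_lab(g1, g2), sqrt(22.4^2 + 0.3^2 + 1.1^2))
  expect_equal(round(delta_e_lab(g1, g2)), 22)
  expect_equal(delta_e_ab(g1, g2), sqrt(0.3^2 + 1.1^2))
  expect_equal(delta_e_lab(g1, g1), 0)
  expect_equal(delta_e_ab(c(50, 3, 4), c(70, 0, 0)), 5)
  # forehead side pair of the darker-vs-lighter modal coordinates
  expect_equal(delta_e_lab(c(59, 22, 20), c(66, 21, 20)), sqrt(50))
})

test_that("delta_e_lab behaves as a metric and dominates delta_e_ab", {
  withr::with_seed(21, {
    for (i in 1:50) {
      x <- as.numeric(c(runif(1, 0, 100), rnorm(2, 0, 30)))
      y <- as.numeric(c(runif(1, 0, 100), rnorm(2, 0, 30)))
      z <- as.numeric(c(runif(1, 0, 100), rnorm(2, 0, 30)))
      expect_equal(delta_e_lab(x, y), delta_e_lab(y, x))
      expect_lte(delta_e_lab(x, z), delta_e_lab(x, y) + delta_e_lab(y, z) + 1e-12)
      expect_lte(delta_e_ab(x, y), delta_e_lab(x, y) + 1e-12)
    }
  })
})

test_that("color differences across observers are refused", {
  lab1 <- structure(data.frame(L = 50, a = 0, b = 0), observer = "cie10deg")
  lab2 <- structure(data.frame(L = 60, a = 0, b = 0), observer = "cie2deg")
  expect_error(delta_e_lab(lab1, lab2), "provenance", ignore.case = TRUE)
})

test_that("rmse_spectra handles constants and rejects grid mismatches", {
  r <- random_spectrum()
  expect_equal(rmse_spectra(r, r), 0)
  shifted <- spectrum(r$wavelength, r$value + 0.05)
  expect_equal(rmse_spectra(r, shifted), 0.05, tolerance = 1e-12)
  expect_error(rmse_spectra(r, spectrum(r$wavelength + 5, r$value)), "grid")
})

test_that("min_reference_spectrum finds the dimmest pixel with stable ties", {
  withr::with_seed(4, {
    mat <- matrix(runif(20 * 31, 0.2, 0.8), 20, 31)
    mat[7, ] <- mat[7, ] * 0.2
    colnames(mat) <- seq(400, 700, 10)
    expect_equal(min_reference_spectrum(mat)$index, 7)
    # exhaustive argmin oracle
    expect_equal(min_reference_spectrum(mat)$index,
                 which.min(sapply(seq_len(nrow(mat)), function(i) mean(mat[i, ]))))
  })
  one <- matrix(0.5, 1, 3, dimnames = list(NULL, c(500, 510, 520)))
  expect_equal(min_reference_spectrum(one)$spectrum$value, rep(0.5, 3))
  tied <- matrix(0.4, 3, 2, dimnames = list(NULL, c(500, 510)))
  expect_equal(min_reference_spectrum(tied)$index, 1)
})

test_that("count_discernible counts occupied unit cells", {
  expect_equal(count_discernible(data.frame(L = c(0.1, 0.9), a = c(0.1, 0.9),
                                            b = c(0.1, 0.9))), 1)
  expect_equal(count_discernible(data.frame(L = 5.5, a = 1.5, b = -2.5)), 1)
  grid3 <- expand.grid(L = 0:2 + 0.5, a = 0:2 + 0.5, b = 0:2 + 0.5)
  expect_equal(count_discernible(grid3), 27)
  expect_equal(count_discernible(grid3, "ab_area"), 9)
  expect_error(count_discernible(data.frame(L = NaN, a = 0, b = 0)), "finite")
})

test_that("gof_nrmse implements the cost-ratio and fit conventions", {
  r <- random_spectrum()
  expect_equal(gof_nrmse(r, r), 0)
  const <- spectrum(r$wavelength, rep(mean(r$value), nrow(r)))
  expect_equal(gof_nrmse(const, r), 1, tolerance = 1e-12)
  expect_equal(gof_nrmse(const, r, "fit"), 0, tolerance = 1e-12)
  expect_error(gof_nrmse(r, const), "constant")
  # brute-force two-norm oracle
  withr::with_seed(14, {
    a <- random_spectrum(); b <- random_spectrum()
    num <- sqrt(sum((a$value - b$value)^2))
    den <- sqrt(sum((b$value - mean(b$value))^2))
    expect_equal(gof_nrmse(a, b), num / den, tolerance = 1e-14)
  })
})

test_that("sRGB rendering maps flat spectra to neutral tones", {
  white <- render_srgb(uniform_cube(flat33(1), 2, 2))
  expect_true(all(white == 255))
  black <- render_srgb(uniform_cube(flat33(0), 2, 2))
  expect_true(all(black == 0))
  gray <- render_srgb(uniform_cube(flat33(0.431), 2, 2))
  expect_lte(max(gray) - min(gray), 1) # R = G = B within one count
  expect_gt(gray[1, 1, 1], 150) # mid-gray, gamma-encoded
})
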