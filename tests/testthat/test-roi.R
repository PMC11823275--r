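uniform_face_cube <- function(value = 0.4, nr = 120, nc = 120, nb = 5) {
  wl <- seq(400, 720, 80)
  spectral_cube(array(value, c(nr, nc, nb)), wl, "reflectance")
}

test_that("circular ROI extraction follows the center-in lattice rule", {
  cube <- spectral_cube(array(0.4, c(120, 120, 33)), hs_wl33, "reflectance")
  lay <- facial_layout(dim = c(120, 120))
  lay$tsr_positions$center_row <- 60
  lay$tsr_positions$center_col <- 60
  lay$tsr_positions$radius_px <- 50
  roi <- extract_roi(cube, lay, 5)
  # brute-force lattice count: integer offsets with x^2 + y^2 <= 50^2
  brute <- sum(outer(-50:50, -50:50, function(x, y) x^2 + y^2) <= 50^2)
  expect_equal(brute, 7845)
  expect_equal(roi$n_pixels, brute)
  # a sub-pixel radius selects only the center pixel
  lay$tsr_positions$radius_px <- 0.6
  expect_equal(extract_roi(cube, lay, 5)$n_pixels, 1)
  # uniform cube: mean spectrum equals any pixel's spectrum
  expect_equal(roi$mean_spectrum$value, rep(0.4, 33))
  # out-of-bounds circles are rejected
  lay$tsr_positions$radius_px <- 80
  expect_error(extract_roi(cube, lay, 5), "bounds")
})

test_that("SPM point aggregation averages the mapped points", {
  lay <- facial_layout()
  wl <- seq(400, 700, 10)
  flat <- function(x) spectrum(wl, rep(x, 31))
  # all identical: every area returns the common spectrum
  same <- setNames(replicate(32, flat(0.37), simplify = FALSE), as.character(1:32))
  nine <- combine_spm_points(same, lay)
  expect_length(nine, 9)
  expect_equal(nine$P3$value, rep(0.37, 31))
  # area 1 averages points 1 and 5
  mixed <- same
  mixed[["1"]] <- flat(0.4); mixed[["5"]] <- flat(0.6)
  expect_equal(combine_spm_points(mixed, lay)$P1$value, rep(0.5, 31))
  # missing points are named in the error
  expect_error(combine_spm_points(same[as.character(1:30)], lay), "31, 32")
})

test_that("SPM aggregation matches a per-wavelength loop oracle and commutes with regridding", {
  lay <- facial_layout()
  wl4 <- seq(400, 700, 4)
  withr::with_seed(19, {
    specs <- setNames(replicate(32, spectrum(wl4, runif(length(wl4), 0.1, 0.8)),
                                simplify = FALSE), as.character(1:32))
  })
  nine <- combine_spm_points(specs, lay)
  for (p in c(1, 4, 9)) {
    members <- lay$spm_to_tsr$spm_id[lay$spm_to_tsr$tsr_id == p]
    oracle <- sapply(seq_along(wl4), function(k) {
      mean(sapply(members, function(m) specs[[as.character(m)]]$value[k]))
    })
    expect_equal(nine[[paste0("P", p)]]$value, oracle, tolerance = 1e-14)
  }
  # combine-then-regrid equals regrid-then-combine (linear operations commute)
  target <- seq(400, 700, 10)
  a <- regrid_spectrum(nine$P2, target)
  b <- combine_spm_points(lapply(specs, regrid_spectrum, target = target), lay)$P2
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("device comparison is zero for self and reflects constant offsets", {
  sc <- symmetric_scene()
  refl <- recover_reflectance(sc, noise = FALSE)
  roi <- extract_roi(refl, sc$layout, 5, face_id = "f1")
  self <- device_comparison(roi, tsr = roi$mean_spectrum)
  expect_equal(self$rmse, 0)
  expect_equal(self$delta_e_lab, 0)
  offset <- spectrum(roi$mean_spectrum$wavelength, roi$mean_spectrum$value + 0.05)
  expect_equal(device_comparison(roi, spm = offset)$rmse, 0.05, tolerance = 1e-6)
})

test_that("a biased contact device reads farther from the imaging data than an unbiased one", {
  scenes <- make_cohort(4, 0.25, seed = 6, dim = c(96, 128))
  rows <- purrr::map_dfr(scenes, function(sc) {
    refl <- recover_reflectance(sc, noise = FALSE)
    purrr::map_dfr(c(2, 5, 9), function(p) {
      roi <- extract_roi(refl, sc$layout, p)
      tsr <- simulate_device_readings(sc, "TSR", p, bias = 1)
      spm_all <- setNames(purrr::map(1:32, function(q) {
        simulate_device_readings(sc, "SPM", q, bias = 1.1)
      }), as.character(1:32))
      spm9 <- combine_spm_points(spm_all, sc$layout)
      device_comparison(roi, tsr = tsr, spm = spm9[[paste0("P", p)]])
    })
  })
  agg <- tapply(rows$rmse, rows$device, mean)
  expect_gt(agg[["SPM"]], agg[["TSR"]])
})

test_that("side comparison is exactly zero on symmetric faces and grows with asymmetry", {
  sc <- symmetric_scene()
  refl <- recover_reflectance(sc, noise = FALSE)
  side <- side_comparison(extract_all_rois(refl, sc$layout))
  expect_equal(side$delta_e_lab, rep(0, 4))
  expect_equal(side$delta_e_ab, rep(0, 4))
  # one-sided melanin increments produce monotonically growing contrasts
  de13 <- sapply(c(0.05, 0.15, 0.3), function(asym) {
    sca <- synthetic_scene(seed = 7, dim = c(96, 128), het_amplitude = 0,
                           gain_amplitude = 0, read_sigma = 0, shot_scale = 0,
                           melanin_asymmetry = asym)
    r <- recover_reflectance(sca, noise = FALSE)
    s <- side_comparison(extract_all_rois(r, sca$layout))
    s$delta_e_lab[s$comparison == "P1 vs P3"]
  })
  expect_true(all(de13 > 0))
  expect_true(all(diff(de13) > 0))
})

test_that("side-comparison pairs match direct delta E evaluation", {
  sc <- tiny_scene(seed = 31, dim = c(96, 128))
  refl <- recover_reflectance(sc, noise = FALSE)
  rois <- extract_all_rois(refl, sc$layout)
  side <- side_comparison(rois)
  for (k in 1:3) {
    pr <- list(c(1, 3), c(4, 6), c(7, 8))[[k]]
    expect_equal(side$delta_e_lab[k],
                 delta_e_lab(rois[[pr[1]]]$mean_lab, rois[[pr[2]]]$mean_lab))
  }
})

test_that("normalized histograms report unit modal frequency and integer peaks", {
  h <- normalized_histogram(rep(42.3, 10))
  expect_equal(nrow(h$bins), 1)
  expect_equal(h$peak, 42)
  h2 <- normalized_histogram(c(rep(1.0, 10), rep(5.0, 5)))
  expect_equal(h2$peak, 1)
  expect_equal(h2$bins$frequency[h2$bins$center == 1], 1)
  expect_equal(h2$bins$frequency[h2$bins$center == 5], 0.5)
  # a large Gaussian sample peaks at its mean within one bin
  withr::with_seed(99, {
    h3 <- normalized_histogram(rnorm(1e5, mean = 60, sd = 5))
  })
  expect_lte(abs(h3$peak - 60), 1)
  expect_error(normalized_histogram(numeric(0)), "non-empty")
})

test_that("group statistics are translation-consistent and reproduce the worked contrast", {
  base <- tibble::tibble(
    face_id = rep(c("f1", "f2", "f3", "f4"), each = 9),
    group = rep(c("G1", "G1", "G2", "G2"), each = 9),
    position_id = rep(1:9, 4),
    L = c(rnorm(18, 60, 2), rnorm(18, 40, 2)),
    a = rnorm(36, 12, 1), b = rnorm(36, 17, 1)
  )
  # pure L translation between groups: both conventions agree exactly
  shifted <- base
  shifted$L <- ifelse(shifted$group == "G2", shifted$L + 100, shifted$L)
  shifted$a <- 5; shifted$b <- 7
  shifted$L[shifted$group == "G1"] <- 30
  shifted$L[shifted$group == "G2"] <- 55
  gs <- group_statistics(shifted)
  expect_equal(gs$between$delta_e_lab, c(25, 25))
  # one face, identical positions: sd 0
  one <- tibble::tibble(face_id = "f", group = "G1", position_id = 1:9,
                        L = 50, a = 10, b = 12)
  g1 <- group_statistics(one)
  expect_equal(g1$per_group$L_sd, 0)
  expect_equal(g1$per_group$L_mean, 50)
  # the printed group means reproduce the headline contrast
  printed <- tibble::tibble(
    face_id = c("m1", "m2"), group = c("G1", "G2"), position_id = 1,
    L = c(61.8, 39.4), a = c(12.9, 12.6), b = c(17.5, 16.4)
  )
  g2 <- group_statistics(printed)
  expect_equal(round(g2$between$delta_e_lab[1]), 22)
  expect_error(group_statistics(one[0, ]), "non-empty|non-missing")
})
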