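# Synthetic hyperspectral face scenes with known ground truth.
#
# Facial skin reflectance is dominated by melanin and hemoglobin absorption.
# The generator uses a deliberately simple two-chromophore Beer-Lambert
# model: R(lambda) = baseline * exp(-m * A_mel - h * A_hb), with a monotone
# power-law melanin absorbance and a two-peak (542/577 nm oxyhemoglobin)
# Gaussian hemoglobin absorbance. It is a qualitative stand-in - no claim of
# radiative-transfer realism - whose job is to give every downstream stage a
# scene with exact ground truth: smooth within-face chromophore variation,
# two skin-tone groups separated by melanin, an in-scene spectrally flat
# gray reference, illuminant spatial nonuniformity, dark level, read and
# shot noise, and 12-bit quantization with per-band exposures set to 85% of
# full scale.

#' Chromophore absorbance curves
#'
#' `melanin_absorbance()` is a monotone-decreasing power law
#' `(lambda/400)^-3.5`, normalized to 1 at 400 nm. `hemoglobin_absorbance()`
#' is the sum of two equal-height Gaussians (sd 12 nm) centered at the
#' 542 nm and 577 nm oxyhemoglobin bands plus a taller, broader Gaussian at
#' the 415 nm Soret band (without it, synthetic skin reflects far too much
#' blue and renders bluish instead of the red-yellow tones characteristic of
#' real facial skin).
#'
#' @param wavelength Wavelengths in nm.
#' @return Numeric absorbance values (dimensionless, nonnegative).
#' @export
melanin_absorbance <- function(wavelength) (wavelength / 400)^-3.5

#' @rdname melanin_absorbance
#' @export
hemoglobin_absorbance <- function(wavelength) {
  3 * exp(-(wavelength - 415)^2 / (2 * 20^2)) +
    exp(-(wavelength - 542)^2 / (2 * 12^2)) +
    exp(-(wavelength - 577)^2 / (2 * 12^2))
}

.group_config_default <- list(
  G1 = list(melanin = c(0.15, 0.60), hemoglobin = c(1.0, 1.5),
            baseline = c(0.60, 0.68), von_luschan = c(1L, 15L)),
  G2 = list(melanin = c(2.2, 3.2), hemoglobin = c(1.0, 1.5),
            baseline = c(0.60, 0.68), von_luschan = c(16L, 36L)),
  g1_melanin_max = 0.60
)

#' Skin phenotype parameters
#'
#' One face's chromophore parameters: melanin and hemoglobin densities
#' (dimensionless Beer-Lambert scalings, >= 0), a baseline reflectance level
#' in (0, 1], the skin-tone group label (G2 faces are darker and must have a
#' melanin density above the configured G1 upper bound), and a von Luschan
#' score carried as metadata only.
#'
#' @param melanin,hemoglobin Chromophore densities, >= 0.
#' @param baseline Baseline reflectance in (0, 1].
#' @param group `"G1"` (lighter) or `"G2"` (darker).
#' @param von_luschan Integer 1-36, metadata only.
#' @param g1_melanin_max Configured G1 melanin upper bound used to validate
#'   the group invariant.
#' @return A one-row tibble of class `skin_phenotype`.
#' @export
skin_phenotype <- function(melanin, hemoglobin, baseline, group = "G1",
                           von_luschan = NA_integer_,
                           g1_melanin_max = .group_config_default$g1_melanin_max) {
  vals <- c(melanin = melanin, hemoglobin = hemoglobin, baseline = baseline)
  if (any(!is.finite(vals))) abort("Phenotype parameters must be finite.")
  if (melanin < 0 || hemoglobin < 0) abort("Chromophore densities must be >= 0.")
  if (baseline <= 0 || baseline > 1) abort("`baseline` must be in (0, 1].")
  if (!group %in% c("G1", "G2")) abort("`group` must be G1 or G2.")
  if (group == "G2" && melanin <= g1_melanin_max) {
    abort(sprintf("A G2 phenotype requires melanin > %g (the G1 upper bound).",
                  g1_melanin_max))
  }
  if (!is.na(von_luschan) && (von_luschan < 1 || von_luschan > 36)) {
    abort("`von_luschan` must be an integer 1-36.")
  }
  out <- tibble::tibble(melanin = melanin, hemoglobin = hemoglobin,
                        baseline = baseline, group = group,
                        von_luschan = as.integer(von_luschan))
  class(out) <- c("skin_phenotype", class(out))
  out
}

#' Skin reflectance spectrum of a phenotype
#'
#' `R(lambda) = baseline * exp(-melanin * A_mel - hemoglobin * A_hb)`,
#' clipped to \[0, 1\].
#'
#' @param phenotype A [skin_phenotype()].
#' @param grid Wavelength grid in nm, within 380-780 nm.
#' @return A reflectance `hs_spectrum`.
#' @examples
#' skin_reflectance(skin_phenotype(0, 0, 0.6), seq(400, 720, 10)) # flat 0.6
#' @export
skin_reflectance <- function(phenotype, grid = seq(400, 720, 10)) {
  if (!inherits(phenotype, "skin_phenotype")) {
    abort("`phenotype` must be a skin_phenotype.")
  }
  if (min(grid) < 380 || max(grid) > 780) abort("`grid` must lie within 380-780 nm.")
  v <- phenotype$baseline *
    exp(-phenotype$melanin * melanin_absorbance(grid)
        - phenotype$hemoglobin * hemoglobin_absorbance(grid))
  spectrum(grid, pmin(pmax(v, 0), 1), "reflectance")
}

# Smooth standardized random field (white noise, Gaussian-blurred, unit sd).
.smooth_field <- function(nr, nc, smoothness = 8) {
  f <- .blur_plane(matrix(rnorm(nr * nc), nr, nc), min(nr, nc) / smoothness)
  (f - mean(f)) / sd(f)
}

#' Synthetic face scene with ground truth
#'
#' Builds one scene: an elliptical face whose melanin and hemoglobin maps
#' vary smoothly around the face's phenotype values, a dark background, a
#' spectrally flat Munsell-N7-style gray reference patch (reflectance 0.431,
#' the Munsell value-7 luminance factor) near the left image margin, a
#' smooth strictly positive illuminant gain field with mean 1, and the
#' acquisition noise model. Everything stochastic is a pure function of
#' `seed`.
#'
#' @param seed Integer seed; the scene and everything rendered from it are
#'   reproducible given this value.
#' @param dim Spatial size `c(rows, cols)`.
#' @param wavelengths Band wavelengths in nm.
#' @param phenotype A [skin_phenotype()]; by default one is drawn from the
#'   group's parameter ranges.
#' @param group Group to draw from when `phenotype` is NULL.
#' @param illuminant Illuminant spectrum (positive everywhere); default D65.
#' @param het_amplitude Relative amplitude of the smooth within-face
#'   chromophore variation (0 gives a spatially uniform, hence left-right
#'   symmetric, face).
#' @param gain_amplitude Relative amplitude of the illuminant gain field.
#' @param melanin_asymmetry Extra multiplicative melanin on the subject-left
#'   half of the face (0 = symmetric); used to study left-right contrasts.
#' @param read_sigma Additive Gaussian read noise, in counts.
#' @param shot_scale Signal-proportional noise scale: the shot term has
#'   sd `shot_scale * sqrt(signal counts)`.
#' @param dark_level Dark offset in counts added before quantization.
#' @param layout A [facial_layout()]; default layout scaled to `dim`.
#' @param group_config Group parameter ranges (see package defaults).
#' @return An object of class `synthetic_scene` with the ground-truth
#'   reflectance cube (`$truth`), chromophore maps, gain field, illuminant,
#'   face mask, reference-patch definition, noise settings, and layout.
#' @export
synthetic_scene <- function(seed, dim = c(192, 256),
                            wavelengths = seq(400, 720, 10),
                            phenotype = NULL, group = "G1",
                            illuminant = cie_d65(wavelengths),
                            het_amplitude = 0.15, gain_amplitude = 0.08,
                            melanin_asymmetry = 0,
                            read_sigma = 2, shot_scale = 0.5, dark_level = 0,
                            layout = facial_layout(dim),
                            group_config = .group_config_default) {
  nr <- dim[1]; nc <- dim[2]
  assert_spectrum(illuminant, "illuminant")
  S <- regrid_spectrum(illuminant, wavelengths)
  if (any(S$value <= 0)) abort("Illuminant power must be positive at every band.")

  withr::with_seed(as.integer(seed), {
    if (is.null(phenotype)) phenotype <- .draw_phenotype(group, group_config)
    field_m <- .smooth_field(nr, nc)
    field_h <- .smooth_field(nr, nc)
    field_g <- .smooth_field(nr, nc)
  })

  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ctr <- layout$center; ax <- layout$semiaxes
  face <- ((rowg - ctr[1]) / ax[1])^2 + ((colg - ctr[2]) / ax[2])^2 <= 1

  mel <- phenotype$melanin * pmax(1 + het_amplitude * field_m, 0.05)
  hb <- phenotype$hemoglobin * pmax(1 + het_amplitude * field_h, 0.05)
  if (melanin_asymmetry != 0) {
    left <- colg > ctr[2] # subject's left = image right
    mel[left] <- mel[left] * (1 + melanin_asymmetry)
  }

  gain <- 1 + gain_amplitude * pmax(pmin(field_g, 3), -3)
  gain <- gain / mean(gain)
  stopifnot(all(gain > 0))

  # ground-truth reflectance cube
  nb <- length(wavelengths)
  a_mel <- melanin_absorbance(wavelengths)
  a_hb <- hemoglobin_absorbance(wavelengths)
  logr <- -outer(as.vector(mel), a_mel) - outer(as.vector(hb), a_hb)
  refl <- phenotype$baseline * exp(logr)
  refl <- pmin(pmax(refl, 0), 1)
  truth <- array(refl, dim = c(nr, nc, nb))
  bg <- !face
  for (b in seq_len(nb)) {
    plane <- truth[, , b]
    plane[bg] <- 0.08
    truth[, , b] <- plane
  }

  # gray reference patch (spectrally flat) in the left margin
  ref_rows <- seq(max(1L, round(0.10 * nr)), round(0.28 * nr))
  ref_cols <- seq(max(1L, round(0.04 * nc)), round(0.14 * nc))
  truth[ref_rows, ref_cols, ] <- 0.431

  structure(list(
    seed = as.integer(seed), dim = c(nr, nc), wavelengths = wavelengths,
    phenotype = phenotype, group = phenotype$group,
    truth = spectral_cube(truth, wavelengths, "reflectance",
                          metadata = list(ground_truth = TRUE)),
    melanin_map = mel, hemoglobin_map = hb, baseline = phenotype$baseline,
    face_mask = face, gain_field = gain, illuminant = S,
    reference = list(rows = ref_rows, cols = ref_cols, reflectance = 0.431),
    noise = list(read_sigma = read_sigma, shot_scale = shot_scale,
                 bit_depth = 12L),
    dark_level = dark_level, layout = layout
  ), class = "synthetic_scene")
}

.draw_phenotype <- function(group, config) {
  g <- config[[group]]
  skin_phenotype(
    melanin = runif(1, g$melanin[1], g$melanin[2]),
    hemoglobin = runif(1, g$hemoglobin[1], g$hemoglobin[2]),
    baseline = runif(1, g$baseline[1], g$baseline[2]),
    group = group,
    von_luschan = sample(g$von_luschan[1]:g$von_luschan[2], 1),
    g1_melanin_max = config$g1_melanin_max
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene: %d x %d x %d, group %s, melanin %.2f, seed %d>\n",
    x$dim[1], x$dim[2], length(x$wavelengths), x$group,
    x$phenotype$melanin, x$seed))
  invisible(x)
}

.quantize_12bit <- function(x) pmin(pmax(round(x), 0), 4095)

# shared forward model: truth cube -> raw counts cube
.render_counts <- function(scene, truth, noise, seed_offset) {
  nb <- dim(truth)[3]
  S <- scene$illuminant$value
  if (any(S <= 0)) abort("Illuminant power must be positive at every band.")
  full <- 0.85 * 4095
  exposure <- numeric(nb)
  counts <- array(0, dim(truth))
  withr::with_seed(scene$seed + seed_offset, {
    for (b in seq_len(nb)) {
      signal <- scene$gain_field * truth[, , b] * S[b]
      exposure[b] <- full / max(signal)
      noiseless <- exposure[b] * signal
      x <- noiseless + scene$dark_level
      if (noise && (scene$noise$read_sigma > 0 || scene$noise$shot_scale > 0)) {
        x <- x + rnorm(length(x), sd = scene$noise$read_sigma) +
          scene$noise$shot_scale * sqrt(noiseless) * rnorm(length(x))
      }
      counts[, , b] <- .quantize_12bit(x)
    }
  })
  spectral_cube(counts, scene$wavelengths, "raw_counts", exposure = exposure,
                metadata = list(dark_level = scene$dark_level,
                                bit_depth = scene$noise$bit_depth))
}

#' Render a scene to a raw-counts hyperspectral cube
#'
#' Forward acquisition model: for each band the noiseless signal is
#' `exposure * gain_field * truth_reflectance * illuminant`, with the
#' per-band exposure set so the brightest noiseless pixel reads 85% of the
#' 12-bit full scale (0.85 x 4095); the dark level, Gaussian read noise and
#' signal-proportional shot noise are added and the result is rounded and
#' clipped to 0-4095. Deterministic given the scene seed.
#'
#' @param scene A [synthetic_scene()].
#' @param noise If `FALSE`, disables read and shot noise (the dark level and
#'   quantization remain).
#' @return A raw-counts `hs_cube` with `exposure` per band.
#' @export
render_face_cube <- function(scene, noise = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  .render_counts(scene, scene$truth$values, noise, seed_offset = 1L)
}

#' Render a flat white calibration target
#'
#' Renders the same scene geometry with the face replaced by a spatially and
#' spectrally flat target of the given reflectance, under the same illuminant
#' and gain field. This emulates the flat uniform white reference acquisition
#' used to map illuminant spatial nonuniformity.
#'
#' @inheritParams render_face_cube
#' @param reflectance Flat target reflectance.
#' @return A raw-counts `hs_cube`.
#' @export
render_flat_cube <- function(scene, reflectance = 1, noise = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  truth <- array(reflectance, dim(scene$truth$values))
  .render_counts(scene, truth, noise, seed_offset = 2L)
}

#' Generator-side conversion of counts to radiance
#'
#' Divides dark-corrected counts by the per-band exposure stored by the
#' renderer. This is the generator's shortcut for cubes of known exposure
#' (for example the flat white calibration target); real face cubes go
#' through the in-scene gray-reference path ([compute_radiance()]).
#'
#' @param cube Raw-counts `hs_cube` carrying `exposure`.
#' @return A radiance-stage `hs_cube`.
#' @export
counts_to_radiance <- function(cube) {
  assert_cube(cube, "raw_counts")
  if (is.null(cube$exposure)) abort("`cube` carries no per-band exposure.")
  dark <- cube$metadata$dark_level %||% 0
  vals <- pmax(sweep(cube$values - dark, 3, cube$exposure, "/"), 0)
  spectral_cube(vals, cube$wavelengths, "radiance", metadata = cube$metadata)
}

#' Ground-truth radiance of the scene's gray reference
#'
#' The radiance a telespectroradiometer would report from the gray patch:
#' patch reflectance times illuminant times the mean gain over the patch.
#'
#' @param scene A [synthetic_scene()].
#' @return An `hs_spectrum` of kind `"radiance"`.
#' @export
scene_reference_radiance <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  g <- mean(scene$gain_field[scene$reference$rows, scene$reference$cols])
  spectrum(scene$wavelengths,
           scene$reference$reflectance * scene$illuminant$value * g,
           "radiance")
}

#' Simulated point-device readings
#'
#' Averages the ground-truth reflectance over the device's aperture
#' footprint: the TSR (telespectroradiometer) reads one of the nine layout
#' areas on a 380-780 nm, 4 nm grid; the SPM (contact spectrophotometer)
#' reads one of the 32 points on a 400-700 nm, 10 nm grid. A multiplicative
#' bias and additive Gaussian noise emulate inter-device systematics (the
#' diffuse-geometry SPM of the study read consistently higher than the
#' radiance-geometry instruments, which a bias > 1 reproduces).
#'
#' @param scene A [synthetic_scene()].
#' @param device `"TSR"` or `"SPM"`.
#' @param position_id Area id 1-9 (TSR) or point id 1-32 (SPM).
#' @param bias Multiplicative bias (default 1).
#' @param noise_sd Additive noise sd in reflectance units (default 0).
#' @return A reflectance `hs_spectrum` on the device grid.
#' @export
simulate_device_readings <- function(scene, device = c("TSR", "SPM"),
                                     position_id, bias = 1, noise_sd = 0) {
  stopifnot(inherits(scene, "synthetic_scene"))
  device <- match.arg(device)
  if (device == "TSR") {
    pos <- scene$layout$tsr_positions
    grid <- seq(380, 780, 4)
  } else {
    pos <- scene$layout$spm_points
    grid <- seq(400, 700, 10)
  }
  hit <- pos[pos$id == position_id, ]
  if (nrow(hit) != 1) {
    abort(sprintf("Unknown %s position id %s.", device, position_id))
  }
  px <- .circle_pixels(hit$center_row, hit$center_col, hit$radius_px, scene$dim)
  if (length(px$rows) == 0) abort("Empty device footprint.")
  inside <- scene$face_mask[cbind(px$rows, px$cols)]
  if (!all(inside)) abort("Device footprint extends beyond the face.")
  idx <- cbind(px$rows, px$cols)
  m <- scene$melanin_map[idx]; h <- scene$hemoglobin_map[idx]
  r <- scene$baseline *
    exp(-outer(m, melanin_absorbance(grid)) - outer(h, hemoglobin_absorbance(grid)))
  v <- bias * colMeans(pmin(pmax(r, 0), 1))
  if (noise_sd > 0) {
    v <- v + withr::with_seed(
      scene$seed + 97L * position_id + ifelse(device == "TSR", 3L, 5L),
      rnorm(length(v), sd = noise_sd))
  }
  spectrum(grid, v, "reflectance")
}

#' Generate a cohort of synthetic face scenes
#'
#' Draws per-face phenotypes from the group parameter ranges and builds one
#' scene per face. With `n_faces = 29` and `group_mix = 4/29` this mirrors
#' the 25 lighter-skin (G1) / 4 darker-skin (G2) cohort structure of the
#' study the generator emulates.
#'
#' @param n_faces Number of faces (>= 1).
#' @param group_mix Fraction of G2 faces in \[0, 1\].
#' @param seed Integer master seed; all per-face draws derive from it.
#' @param ... Passed to [synthetic_scene()] (e.g. `dim`, `het_amplitude`).
#' @param group_config Group parameter ranges.
#' @return A list of `synthetic_scene` objects, G1 faces first.
#' @export
make_cohort <- function(n_faces, group_mix = 4 / 29, seed = 1, ...,
                        group_config = .group_config_default) {
  if (n_faces < 1) abort("`n_faces` must be >= 1.")
  if (group_mix < 0 || group_mix > 1) abort("`group_mix` must be in [0, 1].")
  n_g2 <- round(n_faces * group_mix)
  groups <- c(rep("G1", n_faces - n_g2), rep("G2", n_g2))
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max %/% 2, n_faces))
  purrr::map2(groups, seeds, function(g, s) {
    synthetic_scene(seed = s, group = g, group_config = group_config, ...)
  })
}
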