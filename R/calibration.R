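# Raw counts -> radiance -> reflectance.
#
# The imaging system is calibrated against an in-scene Munsell N7 gray
# reference: per band, pixel radiance is the pixel's (dark/stray-corrected)
# counts scaled by the ratio of the reference's known radiance (measured
# with a telespectroradiometer) to the mean counts over the reference area.
# Reflectance is radiance divided by the illuminant spectrum, after
# compensating the illuminant's spatial nonuniformity with a gain map
# estimated from a flat white reference acquisition.

#' In-scene reference region
#'
#' Designates the pixels of the gray reference and carries its known
#' radiance spectrum (from an external spectroradiometer measurement, or the
#' generator's ground truth for synthetic scenes).
#'
#' @param rows,cols Parallel vectors of pixel coordinates, or for a
#'   rectangular patch, the row and column index ranges (all combinations
#'   are used when `expand = TRUE`).
#' @param radiance An `hs_spectrum` of kind `"radiance"`.
#' @param expand If `TRUE`, treat `rows`/`cols` as ranges of a rectangle.
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(rows, cols, radiance, expand = TRUE) {
  assert_spectrum(radiance, "radiance")
  if (expand) {
    grid <- expand.grid(row = rows, col = cols)
    rows <- grid$row; cols <- grid$col
  }
  if (length(rows) == 0 || length(rows) != length(cols)) {
    abort("The reference region must be a non-empty set of (row, col) pixels.")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 radiance = radiance),
            class = "reference_region")
}

#' Reference region of a synthetic scene
#'
#' @param scene A [synthetic_scene()].
#' @return A [reference_region()] using the scene's ground-truth reference
#'   radiance.
#' @export
scene_reference_region <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  reference_region(scene$reference$rows, scene$reference$cols,
                   scene_reference_radiance(scene))
}

#' Dark-noise and stray-light correction
#'
#' Subtracts the dark frame and the per-band stray-light level from raw
#' counts, clamping at zero. Clamped pixels are counted in
#' `metadata$n_clamped`.
#'
#' @param raw Raw-counts `hs_cube`.
#' @param dark Dark level: a scalar, a per-band vector, or a rows x cols
#'   frame; must be nonnegative.
#' @param stray Stray-light level: scalar or per-band vector, nonnegative.
#' @return The corrected raw-counts `hs_cube`.
#' @export
correct_raw <- function(raw, dark = 0, stray = 0) {
  assert_cube(raw, "raw_counts", "raw")
  d <- dim(raw$values)
  if (any(dark < 0) || any(stray < 0)) {
    abort("`dark` and `stray` must be nonnegative.")
  }
  v <- raw$values
  if (is.matrix(dark)) {
    if (!all(dim(dark) == d[1:2])) abort("Dark frame shape mismatch.")
    v <- v - as.vector(dark) # recycles over bands
  } else if (length(dark) == d[3]) {
    v <- sweep(v, 3, dark, "-")
  } else if (length(dark) == 1L) {
    v <- v - dark
  } else {
    abort("`dark` must be a scalar, per-band vector, or rows x cols frame.")
  }
  if (length(stray) == d[3]) {
    v <- sweep(v, 3, stray, "-")
  } else if (length(stray) == 1L) {
    v <- v - stray
  } else {
    abort("`stray` must be a scalar or a per-band vector.")
  }
  n_clamped <- sum(v < 0)
  if (n_clamped > 0) {
    inform(sprintf("correct_raw: clamped %d negative value(s) to 0.", n_clamped))
    v[v < 0] <- 0
  }
  md <- raw$metadata
  md$dark_corrected <- TRUE
  md$n_clamped <- n_clamped
  spectral_cube(v, raw$wavelengths, "raw_counts", exposure = raw$exposure,
                metadata = md)
}

#' Radiance from corrected counts via the gray reference
#'
#' Per band, `radiance = counts * ref_radiance / mean(reference counts)`:
#' the known radiance of the in-scene gray reference, divided by the average
#' signal the imager records over it, converts every pixel's counts to
#' radiance. The reference radiance is resampled to the cube's wavelengths
#' if needed.
#'
#' @param corrected Dark/stray-corrected raw-counts `hs_cube`.
#' @param ref A [reference_region()].
#' @return A radiance-stage `hs_cube`.
#' @export
compute_radiance <- function(corrected, ref) {
  assert_cube(corrected, "raw_counts", "corrected")
  if (!inherits(ref, "reference_region")) abort("`ref` must be a reference_region.")
  d <- dim(corrected$values)
  if (max(ref$rows) > d[1] || max(ref$cols) > d[2] ||
      min(ref$rows) < 1 || min(ref$cols) < 1) {
    abort("Reference region exceeds cube bounds.")
  }
  n7 <- regrid_spectrum(ref$radiance, corrected$wavelengths)
  idx <- cbind(ref$rows, ref$cols)
  ref_mean <- vapply(seq_len(d[3]),
                     function(b) mean(corrected$values[, , b][idx]),
                     numeric(1))
  bad <- which(ref_mean <= .hs_eps)
  if (length(bad)) {
    abort(sprintf("Reference mean counts are zero at band(s) %s nm.",
                  paste(corrected$wavelengths[bad], collapse = ", ")))
  }
  vals <- sweep(corrected$values, 3, n7$value / ref_mean, "*")
  md <- corrected$metadata
  md$reference_pixels <- length(ref$rows)
  spectral_cube(vals, corrected$wavelengths, "radiance", metadata = md)
}

#' Illuminant spatial-uniformity map from a flat white reference
#'
#' From a radiance cube of a spatially and spectrally flat white target:
#' the illuminant spectrum is the spatial mean per band, and the gain field
#' is each pixel's band-averaged radiance relative to that mean (a single
#' wavelength-independent spatial compensation map, mean 1).
#'
#' @param flat_cube Radiance-stage `hs_cube` of a flat white target.
#' @return A list with `gain_field` (rows x cols matrix, mean 1) and
#'   `illuminant_spd` (an `hs_spectrum`).
#' @export
estimate_illuminant_field <- function(flat_cube) {
  assert_cube(flat_cube, "radiance", "flat_cube")
  d <- dim(flat_cube$values)
  spd <- apply(flat_cube$values, 3, mean)
  if (any(spd <= .hs_eps)) abort("Zero spatial mean at one or more bands.")
  ratio <- sweep(flat_cube$values, 3, spd, "/")
  gain <- apply(ratio, c(1, 2), mean)
  gain <- gain / mean(gain)
  list(gain_field = gain,
       illuminant_spd = spectrum(flat_cube$wavelengths, spd, "illuminant_power"))
}

#' Reflectance from radiance
#'
#' `R = radiance / (S * gain)` per pixel and band, where `S` is the
#' illuminant spectrum and `gain` the optional spatial compensation map.
#' Values above 1.5 are flagged (specular highlights on nose and cheeks are
#' a real noncontact-measurement phenomenon), never clipped.
#'
#' @param radiance Radiance-stage `hs_cube`.
#' @param illuminant_spd Illuminant `hs_spectrum`, positive at every band.
#' @param gain_field Optional rows x cols gain map (default 1 everywhere).
#' @return A reflectance-stage `hs_cube`.
#' @export
compute_reflectance <- function(radiance, illuminant_spd, gain_field = NULL) {
  assert_cube(radiance, "radiance", "radiance")
  assert_spectrum(illuminant_spd, "illuminant_spd")
  S <- regrid_spectrum(illuminant_spd, radiance$wavelengths)
  if (any(S$value <= 0)) abort("Illuminant power must be positive at every band.")
  v <- sweep(radiance$values, 3, S$value, "/")
  if (!is.null(gain_field)) {
    if (!all(dim(gain_field) == dim(v)[1:2])) abort("Gain field shape mismatch.")
    if (any(gain_field <= 0)) abort("Gain field must be strictly positive.")
    v <- v / as.vector(gain_field)
  }
  md <- radiance$metadata
  n_hi <- sum(v > 1.5)
  if (n_hi > 0) {
    md$n_above_1p5 <- n_hi
    inform(sprintf("compute_reflectance: %d value(s) above 1.5 flagged.", n_hi))
  }
  spectral_cube(v, radiance$wavelengths, "reflectance", metadata = md)
}

#' Point reflectance from a radiance ratio
#'
#' The telespectroradiometer path: measured radiance is proportional to
#' reflectance times illuminant, so the ratio of the skin radiance to the
#' radiance of a barium-sulfate white sample at the same spot is the
#' reflectance (BaSO4 treated as the perfect diffuser).
#'
#' @param skin_radiance,white_radiance Radiance spectra on a common grid;
#'   the white radiance must be positive everywhere.
#' @return A reflectance `hs_spectrum`.
#' @export
reflectance_from_ratio <- function(skin_radiance, white_radiance) {
  assert_spectrum(skin_radiance, "skin_radiance")
  assert_spectrum(white_radiance, "white_radiance")
  assert_same_grid(skin_radiance, white_radiance)
  if (any(white_radiance$value <= 0)) {
    abort("White-reference radiance must be positive at every wavelength.")
  }
  spectrum(skin_radiance$wavelength,
           skin_radiance$value / white_radiance$value, "reflectance")
}

#' Full synthetic acquisition and calibration round trip
#'
#' Renders a scene to raw counts, renders its flat white calibration target,
#' and runs the full calibration chain: dark correction, gray-reference
#' radiance (Eq.-3-style ratio), illuminant field estimation from the flat
#' target, and reflectance recovery with gain compensation.
#'
#' @param scene A [synthetic_scene()].
#' @param noise Disable acquisition noise with `FALSE`.
#' @param illuminant_field `"estimate"` (default) derives the illuminant
#'   spectrum and gain map from a rendered flat white target, the full
#'   experimental procedure; `"truth"` uses the scene's known illuminant and
#'   gain field, isolating the counts-to-reflectance math (useful when
#'   checking the quantization-only error bound).
#' @return A reflectance `hs_cube`; compare against `scene$truth`.
#' @export
recover_reflectance <- function(scene, noise = TRUE,
                                illuminant_field = c("estimate", "truth")) {
  stopifnot(inherits(scene, "synthetic_scene"))
  illuminant_field <- match.arg(illuminant_field)
  raw <- render_face_cube(scene, noise = noise)
  corrected <- correct_raw(raw, dark = scene$dark_level)
  radiance <- compute_radiance(corrected, scene_reference_region(scene))
  if (illuminant_field == "estimate") {
    flat_raw <- render_flat_cube(scene, noise = noise)
    flat_rad <- counts_to_radiance(flat_raw)
    field <- estimate_illuminant_field(flat_rad)
  } else {
    field <- list(gain_field = scene$gain_field,
                  illuminant_spd = spectrum(scene$wavelengths,
                                            scene$illuminant$value,
                                            "illuminant_power"))
  }
  compute_reflectance(radiance, field$illuminant_spd, field$gain_field)
}
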