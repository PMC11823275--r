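# S-CIELAB: spatial CIELAB difference between two images.
#
# Pipeline (Zhang & Wandell 1997): per-pixel XYZ -> fixed linear opponent
# transform (one luminance and two chromatic channels) -> per-channel spatial
# low-pass filtering with sum-of-Gaussians kernels matched to human contrast
# sensitivity (widths scale with samples per degree of visual angle) ->
# inverse transform back to XYZ -> CIELAB -> per-pixel Euclidean delta E.
# On spatially uniform images the kernels integrate to one, so the result
# reduces to plain CIELAB.

# XYZ -> opponent (rows of the matrix give O1 lum, O2 red-green, O3 blue-yellow)
.opp_from_xyz <- matrix(c(0.279, 0.72, -0.107,
                          -0.449, 0.29, -0.077,
                          0.086, -0.59, 0.501),
                        nrow = 3, byrow = TRUE)

# Sum-of-Gaussian kernel parameters: weights and spreads (degrees of visual
# angle, interpreted as Gaussian full width at half maximum).
.opp_kernels <- list(
  list(weight = c(0.921, 0.105, -0.108), spread = c(0.0283, 0.133, 4.336)),
  list(weight = c(0.531, 0.330), spread = c(0.0392, 0.494)),
  list(weight = c(0.488, 0.371), spread = c(0.0536, 0.386))
)

# 1-D convolution along rows of `m` with a unit-sum kernel, replicate padding.
.conv_rows <- function(m, kern) {
  h <- (length(kern) - 1L) %/% 2L
  if (h == 0L) return(m * sum(kern))
  n <- ncol(m)
  padded <- m[, c(rep(1L, h), seq_len(n), rep(n, h)), drop = FALSE]
  out <- matrix(0, nrow(m), n)
  for (k in seq_along(kern)) {
    out <- out + kern[k] * padded[, (k - 1L) + seq_len(n), drop = FALSE]
  }
  out
}

.gauss_kernel <- function(sigma, max_half) {
  half <- min(max(1L, ceiling(4 * sigma)), max_half)
  x <- seq(-half, half)
  k <- exp(-0.5 * (x / max(sigma, 1e-6))^2)
  k / sum(k)
}

# Separable Gaussian blur of one image plane, sd in pixels.
.blur_plane <- function(img, sigma) {
  if (sigma <= 0) return(img)
  kr <- .gauss_kernel(sigma, max_half = nrow(img) - 1L)
  kc <- .gauss_kernel(sigma, max_half = ncol(img) - 1L)
  t(.conv_rows(t(.conv_rows(img, kc)), kr))
}

# Composite sum-of-Gaussians filter, weights renormalized to unit DC gain.
.csf_filter <- function(img, weight, spread, sppd) {
  fwhm_to_sd <- 1 / (2 * sqrt(2 * log(2)))
  acc <- 0
  for (i in seq_along(weight)) {
    acc <- acc + weight[i] * .blur_plane(img, spread[i] * sppd * fwhm_to_sd)
  }
  acc / sum(weight)
}

#' S-CIELAB image color difference
#'
#' Computes the spatial CIELAB difference between two reflectance cubes of
#' identical shape: color differences are judged in the context of the image
#' by low-pass filtering opponent-color channels according to the spatial
#' sensitivity of the human eye before converting to CIELAB. Uses the CIE
#' 1931 2-degree observer and (by default) D65, as in conventional S-CIELAB
#' renderings.
#'
#' @param cube1,cube2 Reflectance `hs_cube`s with identical dimensions.
#' @param samples_per_degree Image sampling density in pixels per degree of
#'   visual angle; the default 60 corresponds to one arcminute per pixel.
#' @param illuminant Illuminant spectrum; default CIE D65.
#' @return A list with `delta_e_map` (rows x cols matrix) and `mean_delta_e`.
#' @export
scielab_delta <- function(cube1, cube2, samples_per_degree = 60,
                          illuminant = cie_d65()) {
  assert_cube(cube1, "reflectance", "cube1")
  assert_cube(cube2, "reflectance", "cube2")
  if (!identical(dim(cube1$values), dim(cube2$values))) {
    abort("`cube1` and `cube2` must have identical dimensions.")
  }
  if (samples_per_degree <= 0) abort("`samples_per_degree` must be positive.")
  d <- dim(cube1$values)

  filtered_lab <- function(cube) {
    res <- .spectra_to_xyz(cube_spectra_matrix(cube), cube$wavelengths,
                           illuminant, "cie2deg")
    opp <- res$xyz %*% t(.opp_from_xyz)
    for (ch in 1:3) {
      plane <- matrix(opp[, ch], d[1], d[2])
      pars <- .opp_kernels[[ch]]
      opp[, ch] <- as.vector(.csf_filter(plane, pars$weight, pars$spread,
                                         samples_per_degree))
    }
    xyz_f <- opp %*% t(solve(.opp_from_xyz))
    xyz_f[xyz_f < 0] <- 0 # filtering can ring slightly negative
    xyz_to_lab(xyz_f, res$white)
  }

  lab1 <- filtered_lab(cube1)
  lab2 <- filtered_lab(cube2)
  de <- matrix(sqrt(rowSums((lab1 - lab2)^2)), d[1], d[2])
  list(delta_e_map = de, mean_delta_e = mean(de))
}

#' Build a uniform cube replicating one spectrum
#'
#' Helper for image-context comparisons: expands a single reflectance
#' spectrum (e.g. a device reading or a within-area minimum) into a cube of
#' the same spatial size as the area it is compared against.
#'
#' @param s Reflectance `hs_spectrum`.
#' @param nrow,ncol Spatial size.
#' @return A reflectance `hs_cube`.
#' @export
uniform_cube <- function(s, nrow, ncol) {
  assert_spectrum(s, "s")
  vals <- array(rep(s$value, each = nrow * ncol), dim = c(nrow, ncol, nrow(s)))
  spectral_cube(vals, s$wavelength, "reflectance")
}
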