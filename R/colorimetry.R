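#' Tristimulus integration of a reflectance spectrum
#'
#' Computes CIE XYZ by rectangle-rule summation at the working wavelength
#' step, `X = k * sum(R * S * xbar)`, with `k` chosen so the perfect
#' reflector has `Y = 100`. The illuminant and observer tables are resampled
#' onto the reflectance grid, which must cover at least 400-700 nm.
#'
#' @param r Reflectance `hs_spectrum`.
#' @param illuminant Illuminant `hs_spectrum`; default CIE D65.
#' @param observer Observer name for [get_observer()].
#' @return Named numeric vector `c(X, Y, Z)` with attribute `white` (the
#'   illuminant white point, same normalization) and `provenance`.
#' @examples
#' reflectance_to_xyz(spectrum(seq(400, 720, 10), rep(1, 33)))["Y"] # 100
#' @export
reflectance_to_xyz <- function(r, illuminant = cie_d65(), observer = "cie10deg") {
  assert_spectrum(r, "r")
  if (min(r$wavelength) > 400 + 1e-9 || max(r$wavelength) < 700 - 1e-9) {
    abort("Reflectance grid must cover at least 400-700 nm.")
  }
  xyz <- .spectra_to_xyz(matrix(r$value, nrow = 1), r$wavelength,
                         illuminant, observer)
  out <- setNames(as.numeric(xyz$xyz[1, ]), c("X", "Y", "Z"))
  attr(out, "white") <- xyz$white
  attr(out, "provenance") <- xyz$provenance
  out
}

# Vectorized core: spectra as rows -> XYZ matrix (n x 3), plus white point.
.spectra_to_xyz <- function(mat, wl, illuminant = cie_d65(), observer = "cie10deg") {
  assert_spectrum(illuminant, "illuminant")
  S <- regrid_spectrum(illuminant, wl)$value
  cmf <- get_observer(observer, wl)
  W <- cbind(S * cmf$xbar, S * cmf$ybar, S * cmf$zbar)
  k <- 100 / sum(W[, 2])
  xyz <- (mat %*% W) * k
  colnames(xyz) <- c("X", "Y", "Z")
  list(xyz = xyz, white = c(X = k * sum(W[, 1]), Y = 100, Z = k * sum(W[, 3])),
       provenance = list(observer = attr(cmf, "observer"),
                         illuminant = "as supplied"))
}

# CIELAB f(t): cube root above (24/116)^3, linear below (CIE 15).
.lab_f <- function(t) {
  thr <- (24 / 116)^3
  ifelse(t > thr, t^(1 / 3), t * (841 / 108) + 16 / 116)
}

#' CIELAB coordinates from tristimulus values
#'
#' Standard CIELAB with the two-branch transfer function: cube root above
#' `(24/116)^3` and the linear branch `(841/108) t + 16/116` below it.
#'
#' @param xyz Numeric `c(X, Y, Z)`, or an n x 3 matrix of rows.
#' @param white Reference white `c(Xn, Yn, Zn)` with `Yn = 100`; defaults to
#'   the `white` attribute attached by [reflectance_to_xyz()].
#' @return Named numeric `c(L, a, b)` (or an n x 3 matrix).
#' @export
xyz_to_lab <- function(xyz, white = attr(xyz, "white")) {
  if (is.null(white)) abort("A reference white is required.")
  if (abs(white[2] - 100) > 1e-6) abort("The reference white must have Y = 100.")
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  if (any(m < -1e-9)) abort("Negative tristimulus values are not physical.")
  fx <- .lab_f(m[, 1] / white[1])
  fy <- .lab_f(m[, 2] / white[2])
  fz <- .lab_f(m[, 3] / white[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (!is.matrix(xyz)) out <- setNames(as.numeric(out[1, ]), c("L", "a", "b"))
  out
}

#' CIELAB coordinates of a reflectance spectrum
#'
#' Convenience wrapper: [reflectance_to_xyz()] then [xyz_to_lab()] against
#' the illuminant's own white point.
#'
#' @inheritParams reflectance_to_xyz
#' @return Named numeric `c(L, a, b)`.
#' @export
lab_from_spectrum <- function(r, illuminant = cie_d65(), observer = "cie10deg") {
  xyz <- reflectance_to_xyz(r, illuminant, observer)
  xyz_to_lab(xyz)
}

#' Per-pixel CIELAB of a reflectance cube
#'
#' @param cube Reflectance `hs_cube`.
#' @param rows,cols Optional pixel subset (parallel vectors).
#' @inheritParams reflectance_to_xyz
#' @return A tibble with columns `row`, `col`, `L`, `a`, `b` and attributes
#'   `observer` and `illuminant` recording provenance.
#' @export
cube_to_lab <- function(cube, rows = NULL, cols = NULL,
                        illuminant = cie_d65(), observer = "cie10deg") {
  assert_cube(cube, "reflectance")
  d <- dim(cube$values)
  if (is.null(rows)) {
    rows <- rep(seq_len(d[1]), times = d[2])
    cols <- rep(seq_len(d[2]), each = d[1])
  }
  mat <- cube_spectra_matrix(cube, rows, cols)
  xyz <- .spectra_to_xyz(mat, cube$wavelengths, illuminant, observer)
  lab <- xyz_to_lab(xyz$xyz, xyz$white)
  out <- tibble::tibble(row = rows, col = cols,
                        L = lab[, "L"], a = lab[, "a"], b = lab[, "b"])
  attr(out, "observer") <- observer
  attr(out, "illuminant") <- spectrum_kind(illuminant)
  out
}

.lab_coords <- function(x, arg = "lab") {
  if (is.data.frame(x)) {
    if (!all(c("L", "a", "b") %in% names(x))) {
      abort(sprintf("`%s` must have columns L, a, b.", arg))
    }
    cbind(x$L, x$a, x$b)
  } else if (is.numeric(x) && length(x) == 3) {
    matrix(x, nrow = 1)
  } else if (is.matrix(x) && ncol(x) == 3) {
    x
  } else {
    abort(sprintf("`%s` must be c(L, a, b), an n x 3 matrix, or a data frame.", arg))
  }
}

.check_provenance <- function(c1, c2) {
  o1 <- attr(c1, "observer"); o2 <- attr(c2, "observer")
  if (!is.null(o1) && !is.null(o2) && !identical(o1, o2)) {
    abort("Color difference across observers is not defined; provenance mismatch.")
  }
}

#' CIELAB color differences
#'
#' `delta_e_lab()` is the Euclidean CIELAB difference
#' `sqrt(dL^2 + da^2 + db^2)`; `delta_e_ab()` drops the lightness term and
#' uses only the `a*`, `b*` chromatic plane. Inputs may be `c(L, a, b)`
#' vectors, n x 3 matrices, or data frames with `L`, `a`, `b` columns
#' (vectorized row-wise). If both inputs carry an `observer` attribute it
#' must match.
#'
#' @param c1,c2 CIELAB coordinates (see Details).
#' @return Numeric vector of color differences in CIELAB units.
#' @examples
#' delta_e_lab(c(61.8, 12.9, 17.5), c(39.4, 12.6, 16.4)) # about 22.4
#' @export
delta_e_lab <- function(c1, c2) {
  .check_provenance(c1, c2)
  m1 <- .lab_coords(c1, "c1"); m2 <- .lab_coords(c2, "c2")
  if (nrow(m1) != nrow(m2)) abort("`c1` and `c2` must have the same number of colors.")
  sqrt(rowSums((m1 - m2)^2))
}

#' @rdname delta_e_lab
#' @export
delta_e_ab <- function(c1, c2) {
  .check_provenance(c1, c2)
  m1 <- .lab_coords(c1, "c1"); m2 <- .lab_coords(c2, "c2")
  if (nrow(m1) != nrow(m2)) abort("`c1` and `c2` must have the same number of colors.")
  sqrt(rowSums((m1[, 2:3, drop = FALSE] - m2[, 2:3, drop = FALSE])^2))
}

#' Root-mean-square error between two spectra
#'
#' `sqrt(sum((r1 - r2)^2) / N)` on a common wavelength grid. `N` defaults to
#' the number of wavelength samples, making the value a per-band RMS
#' difference in reflectance units; any positive normalizer can be supplied
#' instead (the definition leaves the normalizer to the analyst).
#'
#' @param r1,r2 Spectra on a common grid.
#' @param n Normalizer; defaults to the number of wavelength samples.
#' @return Dimensionless RMSE.
#' @export
rmse_spectra <- function(r1, r2, n = NULL) {
  assert_spectrum(r1, "r1"); assert_spectrum(r2, "r2")
  assert_same_grid(r1, r2)
  n <- n %||% nrow(r1)
  if (n <= 0) abort("`n` must be positive.")
  sqrt(sum((r1$value - r2$value)^2) / n)
}

#' Minimum-reflectance reference spectrum of a pixel cloud
#'
#' Returns the spectrum of the pixel with minimal band-averaged reflectance;
#' it serves as the within-area reference that every other pixel is compared
#' against when mapping local spectral variation. Ties break to the lowest
#' pixel index.
#'
#' @param mat Numeric matrix of spectra, one row per pixel.
#' @param wavelengths Wavelengths (nm) for the columns of `mat`.
#' @return A list with `spectrum` (an `hs_spectrum`) and `index` (row of `mat`).
#' @export
min_reference_spectrum <- function(mat, wavelengths = as.numeric(colnames(mat))) {
  if (!is.matrix(mat) || nrow(mat) < 1) abort("`mat` must be a non-empty matrix.")
  idx <- which.min(rowMeans(mat)) # which.min already takes the first tie
  list(spectrum = spectrum(wavelengths, mat[idx, ], "reflectance"),
       index = as.integer(idx))
}

#' Count discernible colors by unit-cell occupancy
#'
#' Segments CIELAB space into unit cubes (or the `a*`,`b*` plane into unit
#' squares) anchored at the integer lattice, and counts occupied cells: a
#' proxy for the number of just-noticeably-different colors in a cloud.
#'
#' @param points Data frame with `L`, `a`, `b` columns, or an n x 3 matrix.
#' @param dims `"lab_volume"` (3-D count) or `"ab_area"` (2-D, ignores `L`).
#' @return Integer count of non-empty unit cells.
#' @examples
#' count_discernible(data.frame(L = c(0.1, 0.9), a = c(0.1, 0.9), b = c(0.1, 0.9)))
#' @export
count_discernible <- function(points, dims = c("lab_volume", "ab_area")) {
  dims <- match.arg(dims)
  m <- .lab_coords(points, "points")
  if (nrow(m) == 0) abort("`points` must be non-empty.")
  if (any(!is.finite(m))) abort("Non-finite CIELAB coordinates.")
  f <- floor(m)
  key <- if (dims == "lab_volume") {
    paste(f[, 1], f[, 2], f[, 3])
  } else {
    paste(f[, 2], f[, 3])
  }
  length(unique(key))
}

#' NRMSE goodness of fit between two spectra
#'
#' The normalized root-mean-square-error cost ratio
#' `||test - ref|| / ||ref - mean(ref)||` (`convention = "ratio"`, the
#' default): 0 for a perfect match, 1 when the test does no better than the
#' reference's own mean, above 1 when it does worse. `convention = "fit"`
#' returns `1 - ratio` (the bounded-above-by-1 "fit percentage" variant).
#'
#' @param test,ref Spectra on a common grid; `ref` must be non-constant.
#' @param convention `"ratio"` or `"fit"`.
#' @return Dimensionless goodness-of-fit value.
#' @export
gof_nrmse <- function(test, ref, convention = c("ratio", "fit")) {
  convention <- match.arg(convention)
  assert_spectrum(test, "test"); assert_spectrum(ref, "ref")
  assert_same_grid(test, ref)
  den <- sqrt(sum((ref$value - mean(ref$value))^2))
  if (den < .hs_eps) abort("`ref` is constant; the NRMSE denominator is zero.")
  ratio <- sqrt(sum((test$value - ref$value)^2)) / den
  if (convention == "ratio") ratio else 1 - ratio
}

# XYZ (white-relative) -> 8-bit sRGB, vectorized over rows.
.xyz_to_srgb8 <- function(xyz, white) {
  # rescale so the scene white maps to the sRGB D65 white point
  rel <- sweep(xyz, 2, white, "/")
  xyz_s <- sweep(rel, 2, c(0.95047, 1, 1.08883), "*")
  M <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                -0.9692660, 1.8760108, 0.0415560,
                0.0556434, -0.2040259, 1.0572252),
              nrow = 3, byrow = TRUE)
  lin <- xyz_s %*% t(M)
  lin <- pmin(pmax(lin, 0), 1)
  g <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  matrix(as.integer(round(255 * g)), ncol = 3)
}

#' Render a reflectance cube to an 8-bit sRGB image
#'
#' Per-pixel tristimulus integration (CIE 1931 2-degree observer by default,
#' D65), balanced so that a spectrally flat reflectance renders neutral, then
#' the standard XYZ-to-linear-sRGB matrix, gamma encoding, and clipping.
#'
#' @param cube Reflectance `hs_cube`.
#' @param illuminant Rendering illuminant; default CIE D65.
#' @param observer Rendering observer; default `"cie2deg"`.
#' @return Integer array rows x cols x 3 with values 0-255.
#' @export
render_srgb <- function(cube, illuminant = cie_d65(), observer = "cie2deg") {
  assert_cube(cube, "reflectance")
  d <- dim(cube$values)
  mat <- cube_spectra_matrix(cube)
  res <- .spectra_to_xyz(mat, cube$wavelengths, illuminant, observer)
  rgb8 <- .xyz_to_srgb8(res$xyz, res$white)
  array(rgb8, dim = c(d[1], d[2], 3))
}
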