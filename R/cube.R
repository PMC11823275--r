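#' Hyperspectral cube container
#'
#' An `hs_cube` holds a rows x cols x bands array together with its
#' wavelength axis (nm, strictly increasing), a processing `stage`
#' (`"raw_counts"`, `"radiance"`, or `"reflectance"`), the per-band exposure
#' used at acquisition (raw stage), and free-form metadata. The coordinate
#' convention is (row, col) with row 1 at the image top.
#'
#' Reflectance cubes tolerate values in \[0, 1.5\]: specular highlights on
#' non-flat skin (nose, cheeks) can push recovered reflectance above 1, so
#' values above 1 are counted and flagged in `metadata$n_above_one` rather
#' than clipped.
#'
#' @param values 3-D numeric array, rows x cols x bands.
#' @param wavelengths Numeric vector of band wavelengths in nm, strictly
#'   increasing, length equal to `dim(values)[3]`.
#' @param stage Processing stage.
#' @param exposure Optional per-band exposure scalars (raw stage).
#' @param metadata Named list of free-form metadata.
#' @return An object of class `hs_cube`.
#' @export
spectral_cube <- function(values, wavelengths,
                          stage = c("raw_counts", "radiance", "reflectance"),
                          exposure = NULL, metadata = list()) {
  stage <- match.arg(stage)
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array (rows x cols x bands).")
  }
  if (length(wavelengths) != dim(values)[3]) {
    abort(sprintf("Header lists %d wavelengths but the data has %d bands.",
                  length(wavelengths), dim(values)[3]))
  }
  if (any(diff(wavelengths) <= 0)) abort("Wavelengths must be strictly increasing.")
  if (!is.null(exposure) && length(exposure) != dim(values)[3]) {
    abort("`exposure` must have one scalar per band.")
  }
  if (stage == "reflectance") {
    if (any(!is.finite(values))) abort("Reflectance cubes must be finite.")
    n_hi <- sum(values > 1)
    if (n_hi > 0) metadata$n_above_one <- n_hi
    if (any(values > 1.5) || any(values < 0)) {
      warn(sprintf(
        "Reflectance outside [0, 1.5] at %d value(s); kept, but check calibration.",
        sum(values > 1.5 | values < 0)))
    }
  }
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 stage = stage, exposure = exposure, metadata = metadata),
            class = "hs_cube")
}

#' @export
print.hs_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hs_cube: %d x %d px, %d bands (%g-%g nm), stage %s>\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$stage))
  invisible(x)
}

#' @export
dim.hs_cube <- function(x) dim(x$values)

is_cube <- function(x) inherits(x, "hs_cube")

assert_cube <- function(x, stage = NULL, arg = "cube") {
  if (!is_cube(x)) abort(sprintf("`%s` must be an hs_cube.", arg))
  if (!is.null(stage) && !(x$stage %in% stage)) {
    abort(sprintf("`%s` must be at stage %s (got %s).", arg,
                  paste(stage, collapse = "/"), x$stage))
  }
  invisible(x)
}

#' Extract the spectrum of one pixel
#'
#' @param cube An `hs_cube`.
#' @param row,col Pixel coordinates (1-based, row 1 at image top).
#' @return An `hs_spectrum` whose kind matches the cube stage
#'   (raw counts are returned as "radiance"-kind numbers for plotting).
#' @export
pixel_spectrum <- function(cube, row, col) {
  assert_cube(cube)
  d <- dim(cube$values)
  if (row < 1 || row > d[1] || col < 1 || col > d[2]) abort("Pixel out of bounds.")
  kind <- switch(cube$stage, reflectance = "reflectance", "radiance")
  spectrum(cube$wavelengths, cube$values[row, col, ], kind)
}

#' Flatten cube pixels to a spectra matrix
#'
#' @param cube An `hs_cube`.
#' @param rows,cols Optional parallel vectors of pixel coordinates; default
#'   all pixels in column-major order.
#' @return A numeric matrix, one row per pixel, one column per band.
#' @export
cube_spectra_matrix <- function(cube, rows = NULL, cols = NULL) {
  assert_cube(cube)
  d <- dim(cube$values)
  if (is.null(rows)) {
    m <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  } else {
    stopifnot(length(rows) == length(cols))
    idx <- cbind(rep(rows, d[3]), rep(cols, d[3]),
                 rep(seq_len(d[3]), each = length(rows)))
    m <- matrix(cube$values[idx], nrow = length(rows), ncol = d[3])
  }
  colnames(m) <- cube$wavelengths
  m
}
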