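#' Wavelength-indexed spectra
#'
#' An `hs_spectrum` is a tibble with columns `wavelength` (nm, strictly
#' increasing) and `value`, plus a `kind` attribute saying what the values
#' are: `"reflectance"` (dimensionless, nominally 0-1), `"radiance"`, or
#' `"illuminant_power"` (both in arbitrary linear units). All spectral
#' arithmetic in the package flows through this container.
#'
#' @param wavelength Numeric vector of wavelengths in nm. Rows are sorted by
#'   wavelength on construction; duplicated wavelengths are an error.
#' @param value Numeric vector, same length as `wavelength`.
#' @param kind One of `"reflectance"`, `"radiance"`, `"illuminant_power"`.
#' @return A tibble of class `hs_spectrum` with columns `wavelength`, `value`.
#' @examples
#' s <- spectrum(seq(400, 720, 10), rep(0.431, 33), "reflectance")
#' mean(s$value)
#' @export
spectrum <- function(wavelength, value,
                     kind = c("reflectance", "radiance", "illuminant_power")) {
  kind <- match.arg(kind)
  if (!is.numeric(wavelength) || !is.numeric(value)) {
    abort("`wavelength` and `value` must be numeric.")
  }
  if (length(wavelength) != length(value)) {
    abort(sprintf("`wavelength` (%d) and `value` (%d) lengths differ.",
                  length(wavelength), length(value)))
  }
  if (length(wavelength) == 0L) abort("A spectrum needs at least one sample.")
  if (anyNA(wavelength) || any(!is.finite(wavelength))) {
    abort("Wavelengths must be finite.")
  }
  if (anyDuplicated(wavelength)) abort("Duplicated wavelengths are not allowed.")
  o <- order(wavelength)
  out <- tibble::tibble(wavelength = as.numeric(wavelength[o]),
                        value = as.numeric(value[o]))
  structure(out, kind = kind,
            class = c("hs_spectrum", class(tibble::tibble())))
}

#' @export
print.hs_spectrum <- function(x, ...) {
  cat(sprintf("<hs_spectrum: %s, %d bands, %g-%g nm>\n",
              spectrum_kind(x), nrow(x), min(x$wavelength), max(x$wavelength)))
  NextMethod()
}

#' @rdname spectrum
#' @param s An `hs_spectrum`.
#' @export
spectrum_kind <- function(s) attr(s, "kind") %||% "reflectance"

is_spectrum <- function(s) inherits(s, "hs_spectrum")

assert_spectrum <- function(s, arg = "spectrum") {
  if (!is_spectrum(s)) abort(sprintf("`%s` must be an hs_spectrum.", arg))
  invisible(s)
}

#' Check that two spectra share a wavelength grid
#' @noRd
assert_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(abs(a$wavelength - b$wavelength) > 1e-9)) {
    abort("Spectra are not on a common wavelength grid; regrid first.")
  }
  invisible(TRUE)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation onto `target`, matching how telespectroradiometer
#' curves (380-780 nm, 4 nm step) are brought onto the common analysis grid
#' (default 400-700 nm in 10 nm steps). Extrapolation outside the source
#' span is refused rather than guessed.
#'
#' @param s An `hs_spectrum`.
#' @param target Numeric vector of target wavelengths (nm), strictly
#'   increasing, within the span of `s`.
#' @return An `hs_spectrum` on the target grid, same kind.
#' @examples
#' tsr <- spectrum(seq(380, 780, 4), seq(380, 780, 4) / 1000, "reflectance")
#' regrid_spectrum(tsr, seq(400, 700, 10))
#' @export
regrid_spectrum <- function(s, target = seq(400, 700, 10)) {
  assert_spectrum(s, "s")
  if (any(diff(target) <= 0)) abort("`target` must be strictly increasing.")
  if (min(target) < min(s$wavelength) - 1e-9 ||
      max(target) > max(s$wavelength) + 1e-9) {
    abort(sprintf(
      "Target grid [%g, %g] extends beyond the source span [%g, %g]; extrapolation is not supported.",
      min(target), max(target), min(s$wavelength), max(s$wavelength)))
  }
  if (length(target) == nrow(s) && all(abs(target - s$wavelength) < 1e-9)) {
    return(s)
  }
  v <- approx(s$wavelength, s$value, xout = target, method = "linear",
              rule = 1, ties = "error")$y
  spectrum(target, v, spectrum_kind(s))
}

#' Read and write two-column spectrum CSV files
#'
#' The on-disk format is `wavelength_nm,value` with an optional header row.
#' Rows are sorted by wavelength on read (a shuffled file is accepted with a
#' message); duplicated wavelengths or non-numeric cells are errors.
#'
#' @param path File path.
#' @param kind Spectrum kind to attach on read (see [spectrum()]).
#' @return `read_spectrum_csv()` returns an `hs_spectrum`;
#'   `write_spectrum_csv()` invisibly returns `path`.
#' @export
read_spectrum_csv <- function(path, kind = "reflectance") {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(raw) < 2) abort("Spectrum CSV must have two columns.")
  # tolerate a header row
  if (is.na(suppressWarnings(as.numeric(raw[1, 1])))) raw <- raw[-1, , drop = FALSE]
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  v <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(wl) | is.na(v))
  if (length(bad)) {
    abort(sprintf("Non-numeric spectrum data at row(s) %s of %s.",
                  paste(head(bad, 5), collapse = ", "), path))
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    inform(sprintf("Wavelengths in %s were not sorted; sorting on read.", path))
  }
  spectrum(wl, v, kind)
}

#' @rdname read_spectrum_csv
#' @param s An `hs_spectrum` to write.
#' @export
write_spectrum_csv <- function(s, path) {
  assert_spectrum(s, "s")
  df <- data.frame(wavelength_nm = s$wavelength, value = s$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
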