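# Standard colorimetric tables, 400-720 nm at 10 nm.
#
# The analysis observer is a 10-degree large-field observer (the study design
# calls for cone-fundamental-based 10-degree color matching functions; the
# values shipped here are the CIE 1964 supplementary observer, which tracks
# the cone-fundamental construction closely over the visible range - see the
# methods vignette). Rendering and S-CIELAB use the CIE 1931 2-degree
# observer. D65 is the standard relative spectral power distribution
# (100 at 560 nm). Tables are stored at the cube's native 10 nm step and
# linearly interpolated onto finer working grids when needed.

.hs_wl <- seq(400, 720, 10)

.cmf_2deg <- cbind(
  xbar = c(0.01431, 0.04351, 0.13438, 0.28390, 0.34828, 0.33620, 0.29080,
           0.19536, 0.09564, 0.03201, 0.00490, 0.00930, 0.06327, 0.16550,
           0.29040, 0.43345, 0.59450, 0.76210, 0.91630, 1.02630, 1.06220,
           1.00260, 0.85445, 0.64240, 0.44790, 0.28350, 0.16490, 0.08740,
           0.04677, 0.02270, 0.01136, 0.00579, 0.00290),
  ybar = c(0.000396, 0.00121, 0.00400, 0.01160, 0.02300, 0.03800, 0.06000,
           0.09098, 0.13902, 0.20802, 0.32300, 0.50300, 0.71000, 0.86200,
           0.95400, 0.99495, 0.99500, 0.95200, 0.87000, 0.75700, 0.63100,
           0.50300, 0.38100, 0.26500, 0.17500, 0.10700, 0.06100, 0.03200,
           0.01700, 0.00821, 0.00410, 0.00209, 0.00105),
  zbar = c(0.06785, 0.20740, 0.64560, 1.38560, 1.74706, 1.77211, 1.66920,
           1.28764, 0.81295, 0.46518, 0.27200, 0.15820, 0.07825, 0.04216,
           0.02030, 0.00875, 0.00390, 0.00210, 0.00165, 0.00110, 0.00080,
           0.00034, 0.00019, 0.00005, 0.00002, 0, 0, 0, 0, 0, 0, 0, 0)
)

.cmf_10deg <- cbind(
  xbar = c(0.019110, 0.084736, 0.204492, 0.314679, 0.383734, 0.370702,
           0.302273, 0.195618, 0.080507, 0.016172, 0.003816, 0.037465,
           0.117749, 0.236491, 0.376772, 0.529826, 0.705224, 0.878655,
           1.014160, 1.118520, 1.123990, 1.030480, 0.856297, 0.647467,
           0.431567, 0.268329, 0.152568, 0.081261, 0.040851, 0.019941,
           0.009577, 0.004553, 0.002145),
  ybar = c(0.002000, 0.008756, 0.021391, 0.038676, 0.062077, 0.089456,
           0.128201, 0.185190, 0.253589, 0.339133, 0.460777, 0.606741,
           0.761757, 0.875211, 0.961988, 0.991761, 0.997340, 0.955552,
           0.868934, 0.777405, 0.658341, 0.527963, 0.398057, 0.283493,
           0.179828, 0.107633, 0.060281, 0.031800, 0.015905, 0.007749,
           0.003718, 0.001768, 0.000846),
  zbar = c(0.086011, 0.389366, 0.972542, 1.553480, 1.967280, 1.994800,
           1.745370, 1.317560, 0.772125, 0.415254, 0.218502, 0.112044,
           0.060709, 0.030451, 0.013676, 0.003988, 0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
)

.d65_spd <- c(82.7549, 91.4860, 93.4318, 86.6823, 104.8650, 117.0080,
              117.8120, 114.8610, 115.9230, 108.8110, 109.3540, 107.8020,
              104.7900, 107.6890, 104.4050, 104.0460, 100.0000, 96.3342,
              95.7880, 88.6856, 90.0062, 89.5991, 87.6987, 83.2886,
              83.6992, 80.0268, 80.2146, 82.2778, 78.2842, 69.7213,
              71.6091, 74.3490, 61.6040)

#' Color matching functions
#'
#' Returns the color matching functions of one of the two observers used in
#' the analysis, resampled (linear interpolation) onto a wavelength grid.
#' `"cie10deg"` is the large-field analysis observer used for all CIELAB
#' statistics; `"cie2deg"` is the CIE 1931 observer used for sRGB rendering
#' and S-CIELAB. Aliases `"CIE2006_10deg"` and `"CIE1931_2deg"` are accepted.
#'
#' @param observer Observer name.
#' @param grid Wavelength grid in nm (within 400-720 nm).
#' @return A tibble with columns `wavelength`, `xbar`, `ybar`, `zbar`.
#' @export
get_observer <- function(observer = c("cie10deg", "cie2deg",
                                      "CIE2006_10deg", "CIE1931_2deg"),
                         grid = .hs_wl) {
  observer <- match.arg(observer)
  tab <- if (observer %in% c("cie10deg", "CIE2006_10deg")) .cmf_10deg else .cmf_2deg
  if (min(grid) < min(.hs_wl) - 1e-9 || max(grid) > max(.hs_wl) + 1e-9) {
    abort("Observer tables cover 400-720 nm; requested grid extends beyond.")
  }
  out <- tibble::tibble(
    wavelength = as.numeric(grid),
    xbar = approx(.hs_wl, tab[, "xbar"], xout = grid)$y,
    ybar = approx(.hs_wl, tab[, "ybar"], xout = grid)$y,
    zbar = approx(.hs_wl, tab[, "zbar"], xout = grid)$y
  )
  attr(out, "observer") <- if (observer %in% c("cie10deg", "CIE2006_10deg"))
    "cie10deg" else "cie2deg"
  out
}

#' CIE D65 illuminant
#'
#' Relative spectral power distribution of CIE standard illuminant D65,
#' resampled onto `grid` (linear interpolation from the 10 nm table).
#'
#' @param grid Wavelength grid in nm (within 400-720 nm).
#' @return An `hs_spectrum` of kind `"illuminant_power"`.
#' @export
cie_d65 <- function(grid = .hs_wl) {
  if (min(grid) < min(.hs_wl) - 1e-9 || max(grid) > max(.hs_wl) + 1e-9) {
    abort("The D65 table covers 400-720 nm; requested grid extends beyond.")
  }
  spectrum(grid, approx(.hs_wl, .d65_spd, xout = grid)$y, "illuminant_power")
}
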