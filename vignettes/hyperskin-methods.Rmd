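---
title: "Hyperspectral facial skin colorimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral facial skin colorimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperskin)
```

## The problem

The perceived color of facial skin is governed by its spectral reflectance,
which is dominated by melanin and hemoglobin absorption and varies strongly
across the face, between facial sides, and between skin tones. Point
instruments — a telespectroradiometer (TSR) reading radiance over roughly a
1 degree field, or a contact spectrophotometer (SPM) with a few-mm aperture —
summarize an area by a single spectrum and therefore hide that spatial
variation. A hyperspectral imaging system (HIS) records a full reflectance
spectrum at every pixel (here 400–720 nm in 10 nm steps), which makes the
local chromatic structure measurable but requires careful calibration:
the raw 12-bit counts must be converted to radiance against an in-scene
Munsell N7 gray reference and to reflectance against the illuminant and its
spatial nonuniformity.

`hyperskin` implements that entire chain — calibration, per-pixel CIELAB
colorimetry, spectral and chromatic difference metrics, discernible-color
volume estimation, nine-position facial statistics, and cross-device
comparison — together with a synthetic face-cube generator with exact
ground truth, so that every stage can be validated end to end without
access to human-subject data.

## Calibration model

For each band $\lambda$, after subtracting the dark level and stray light
(negative results clamp to zero and are counted), pixel radiance is

$$\beta(\lambda) = \beta_\text{image}(\lambda)\,
  \frac{\beta_{N7}(\lambda)}{\beta_\text{reference}(\lambda)},$$

where $\beta_{N7}$ is the gray reference's radiance known from a
spectroradiometer measurement and $\beta_\text{reference}$ is the mean
image signal over the reference area. Reflectance is then

$$R(\lambda) = \frac{\beta(\lambda)}{S(\lambda)\, g(r, c)},$$

with $S(\lambda)$ the illuminant spectrum and $g$ a wavelength-independent
spatial gain map (mean 1) estimated from an acquisition of a flat white
target: $S$ is the white target's spatial mean radiance per band, and $g$ is
each pixel's band-averaged radiance relative to that mean. A single spatial
map (rather than one per band) matches how a stable lamp's geometry factors
out of the spectrum. Recovered reflectance above 1 is flagged, and above
1.5 flagged loudly, but never clipped: specular highlights on the nose and
cheeks genuinely exceed 1 in noncontact geometries and clipping would bias
area statistics.

The TSR path is the simple ratio $R(\lambda) =
\beta_\text{skin}(\lambda) / \beta_{\mathrm{BaSO}_4}(\lambda)$, treating the
barium-sulfate sample as a perfect diffuser.

## Colorimetry

Tristimulus values use rectangle-rule integration at the working step
(10 nm, the cubes' native sampling), normalized so the perfect reflector has
$Y = 100$; CIELAB uses the standard two-branch transfer function. All
area and group statistics assume CIE D65 and a 10-degree large-field
observer; sRGB rendering and S-CIELAB use the CIE 1931 2-degree observer.

Two tabulation choices deserve note.

* **Observer tables.** The analysis calls for cone-fundamental-based
  10-degree color matching functions. No pre-installed source provides that
  table, so the package ships the CIE 1964 10-degree supplementary observer,
  which tracks the cone-fundamental construction closely across the visible
  range; the difference is far below every tolerance used here, and no
  result in the package depends on the distinction (the colorimetric anchors
  are exact by normalization, and all contrasts are relative). Tables are
  stored at 10 nm and interpolated linearly when a finer grid is requested.
* **White balance in rendering.** sRGB rendering rescales tristimulus values
  so the scene's perfect reflector maps exactly to the sRGB white point;
  a spectrally flat patch therefore renders neutral regardless of the small
  chromaticity offset a 10 nm table introduces.

Difference metrics: the spectral RMSE is
$\sqrt{\sum_\lambda \Delta R(\lambda)^2 / N}$. The normalizer $N$ is the
number of wavelength samples by default — the natural per-spectrum reading —
but is exposed as an argument because the quantity is also used summed over
a pixel sample, and the two readings differ only by a constant factor.
$\Delta E_{(L^*,a^*,b^*)}$ and $\Delta E_{(a^*,b^*)}$ are the Euclidean
CIELAB distances with and without the lightness term. The NRMSE goodness of
fit is the cost ratio $\lVert \text{test} - \text{ref}\rVert /
\lVert \text{ref} - \overline{\text{ref}}\rVert$: the ratio convention is
primary because reported values above 1 are meaningful under it (the
"fit" variant $1 - \text{ratio}$ is bounded above by 1 and is exposed as an
option).

Discernible colors are counted by flooring each CIELAB coordinate to the
integer lattice and counting occupied unit cells (3-D volume, or 2-D
$a^*b^*$ area). The lattice is anchored at integers with no sub-cell
offsets; the count is invariant under duplication, monotone under adding
points, bounded by the number of points, and the union of two clouds never
occupies fewer cells than either cloud — properties the test suite checks
on a thousand random clouds.

S-CIELAB follows the Zhang–Wandell construction: a fixed linear opponent
transform, per-channel convolution with unit-sum sums of Gaussians whose
spreads scale with samples per degree (default 60, i.e. one arcminute per
pixel), inverse transform, then per-pixel CIELAB difference. The kernel
spreads are interpreted as Gaussian FWHM in degrees; kernels are truncated
at four standard deviations (or the image size) and renormalized, so
spatially uniform images reduce exactly to plain CIELAB — the DC-preserving
property the tests pin down to $10^{-3}$.

## ROI machinery

Each of the nine facial positions is a circle; pixels whose integer centers
fall inside (center-in rule) belong to the area — a 50-pixel radius selects
7845 lattice pixels, matching the "about 7500 spectra per 100-pixel-diameter
area" protocol scale. An area's summary CIELAB coordinate is the **mean of
the per-pixel Lab values** by default, since group statistics average across
all pixels of each position; the Lab of the mean spectrum is also stored,
and both conventions are always available.

The 32 SPM points aggregate into the nine areas by unweighted per-wavelength
averaging; the grouping is a configurable map whose default follows the
protocol's one documented example (area 1 = mean of points 1 and 5) and a
surrounding-points scheme for the rest. Because averaging and linear
regridding commute, aggregating then regridding equals regridding then
aggregating, which the tests verify to machine precision.

Side labels are anatomical: the subject's right appears on the image left,
and the layout JSON records this convention so users with mirrored data can
flip it. Side pairs are (1,3) forehead, (4,6) cheek, (7,8) jawline, plus the
contrast between the mean of positions (1,4,7) and the mean of (3,6,8).

Between-group color difference is reported under **two orders of
averaging**: the difference of the group-mean coordinates, and the mean of
the pairwise differences between per-face mean coordinates. The two differ
whenever within-group spread is appreciable — with wide lightness spread the
pairwise average is dominated by $|\Delta L^*|$ magnitudes rather than their
signed mean — so a single number would be ambiguous; both are computed.

Normalized histograms use bins of configurable width (default 1 CIELAB
unit) centered on integer multiples of the width, scaled so the modal bin
has frequency 1; the reported peak is the modal bin center rounded to the
nearest integer, with ties breaking to the lowest bin.

## The synthetic scene generator

The generator exists to give the pipeline a ground truth, not to be a skin
optics model. Skin reflectance is a two-chromophore Beer–Lambert form

$$R(\lambda) = R_0 \exp\big(-m\,A_\text{mel}(\lambda)
  - h\,A_\text{hb}(\lambda)\big),$$

with $A_\text{mel}(\lambda) = (\lambda/400)^{-3.5}$ (monotone decreasing,
normalized to 1 at 400 nm) and $A_\text{hb}$ a sum of equal-height Gaussians
at the 542 and 577 nm oxyhemoglobin bands (sd 12 nm) plus a taller, broader
Gaussian at the 415 nm Soret band (height 3, sd 20 nm). The Soret term is a
deliberate addition to the minimal two-band form: without it synthetic skin
reflects far too much blue and comes out with negative $b^*$ (bluish),
contradicting the red–yellow tones real facial skin shows under D65. With
it, rendered faces land at plausible skin chromaticities, although $a^*$
remains lower than typical real-skin values — narrow Gaussian bands cannot
reproduce hemoglobin's broad green absorption, and no conclusion in the
package depends on absolute $a^*$ levels.

A scene consists of an elliptical face on a dark background (flat 0.08
reflectance), a spectrally flat gray reference patch at reflectance 0.431
(the Munsell value-7 luminance factor) near the left margin, smooth
chromophore maps (Gaussian-smoothed white noise, relative amplitude 0.15 by
default), a smooth strictly positive illuminant gain field (mean 1,
amplitude 0.08), and D65 as the default illuminant (any positive spectrum
is accepted). Per band, exposure is set so the brightest noiseless pixel
reads 85% of the 12-bit full scale (3481 counts); read noise (Gaussian,
sd 2 counts) and signal-proportional shot noise (sd $0.5\sqrt{\text{counts}}$,
the shot-noise scale of a low-noise cooled CCD with a gain near
4 e$^-$/count) are added before rounding and clipping to 0–4095. Everything
stochastic is a pure function of the scene seed.

Cohorts draw per-face phenotypes from two groups separated by melanin:
G1 (lighter) melanin $U(0.15, 0.6)$, G2 (darker) $U(2.2, 3.2)$, hemoglobin
$U(1.0, 1.5)$ and baseline $U(0.60, 0.68)$ for both. No quantitative
chromophore values per skin-tone group were available to anchor these; they
were chosen once so that the qualitative structure holds with margin — the
worst-case G1/G2 pairing still differs by about 6 $L^*$ units, so every
darker-group face has lower mean lightness than every lighter-group face,
at every facial position. The default cohort (29 faces, 25 lighter / 4
darker) mirrors the cohort structure of the study this design follows.

**What passing tests do and do not show.** The generator produces smooth
chromophore fields, a linear acquisition with simple Gaussian noise, perfect
in-scene references, and no geometry: no facial shading, no specular lobes,
no movement artifacts, no freckles or vasculature, and Poisson statistics
are approximated by a Gaussian. A green test suite therefore demonstrates
that the *pipeline mathematics* is correct and self-consistent — not that
the generator's spectra match real skin, nor that real acquisitions meet
the round-trip error bounds, which depend on instrument behavior the
generator idealizes.

## Numerical choices and degenerate inputs

* Regridding is linear interpolation; extrapolation outside a spectrum's
  span is refused rather than guessed.
* Negative dark/stray-corrected counts clamp to zero and are counted.
* A zero reference mean at any band aborts calibration, naming the bands.
* The minimum-reflectance reference pixel is the band-averaged argmin; ties
  take the lowest pixel index.
* Histogram peak ties take the lowest bin.
* Division of work sizes: the default cube is 192 x 256 x 33 (the study's
  full 1024 x 1344 frames are supported but not default), chosen so a full
  29-face cohort generates, calibrates, and analyzes in about a minute on
  one CPU; all error bounds in the tests were set from the 12-bit
  quantization model, not from the cube size.

## Limitations

* The 10-degree observer table is the CIE 1964 supplementary observer, not
  the cone-fundamental-based table itself (see above).
* The generator's $a^*$ is low relative to real skin; group contrasts in
  $a^*$, $b^*$ are qualitative only.
* CIEDE2000, chromatic adaptation transforms, and gamut mapping beyond sRGB
  clipping are out of scope, as are facial-landmark detection and
  between-group hypothesis testing (the statistics are descriptive).
* Movement artifacts are deliberately not modeled or corrected: the
  calibration chain assumes a static scene.

## A worked example

```{r example, eval = FALSE}
library(hyperskin)

scene <- synthetic_scene(seed = 1)
refl <- recover_reflectance(scene)           # render + full calibration
rois <- extract_all_rois(refl, scene$layout, face_id = "demo")
summaries_to_tibble(rois)

report <- run_pipeline(analysis_config(n_faces = 8, seed = 1,
                                       dim = c(96L, 128L)))
report
tidy(report$group_stats)
autoplot(report$group_stats)
```
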