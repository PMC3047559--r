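---
title: "Methods: optical simulation and image analysis for a ball-lens phone microscope and a slit-grating phone spectrometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical simulation and image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketscope)
```

# The instruments

`pocketscope` models two attachments that turn a camera phone into a field
instrument:

* a **microscope**: a 1 mm glass ball lens held with a 0.8 mm field aperture
  against the phone camera (a fixed-focus lens of 3.36 mm focal length in
  front of a 3.55 x 2.68 mm CMOS sensor with 2.2 um pixels). A ball lens of
  diameter $D$ and index $n$ has, from its centre, the focal length
  $f = nD / (4(n-1))$; at $n = 1.5168$ and $D = 1$ mm that is 0.734 mm,
  giving roughly 4.6-4.8x magnification onto the sensor. The price of a
  single-element objective is strong field curvature (the surface of best
  focus is a sphere, so a flat sensor sees radially growing defocus) and
  pincushion distortion;
* a **spectrometer**: a 1000 lines/mm transmission grating on the camera
  window, fed by a 77.5 mm baffled tube with ~1 mm slits at both ends. The
  two slits over the tube length set the angular acceptance and hence the
  spectral resolution.

The package implements the computational side of both: a sequential ray
tracer and metric extractor; restoration of the curved-field images by
sum-modified-Laplacian (SML) multifocus fusion and radial distortion
correction; spectrum extraction, wavelength calibration and a slit-grating
forward model; marker-controlled watershed counting of red cells; and seeded
synthetic generators for every input class, so that every pipeline can be
scored against exact ground truth.

# Ray tracing and first-order metrics

The tracer (`trace_ray()`, `spot_metrics()`) propagates exact 3-D rays
through ordered elements: refracting spherical surfaces (vector Snell law;
curvature radius 0 encodes a plane), pure aperture stops, and ideal thin
lenses. Rays that miss an aperture or undergo total internal reflection are
marked dead with a reason rather than raising errors, so throughput
bookkeeping (`launched = surviving + killed`) always balances. Fans from an
object point are deterministic concentric rings at area-uniform radii in
direction space — no RNG anywhere in the optics module, so every metric is
bit-reproducible.

Conventions: the optical axis is +z, the object sits at negative z, all
distances are mm and angles at the API surface are degrees. For the default
train the ball centre is at $z = 0$, so "object distance" reads as distance
from the ball centre.

Three definitional choices deserve explanation, because a ball lens at full
aperture is severely aberrated and naive real-ray numbers are dominated by
that aberration:

* **Source fan and best focus.** The instrument is used in
  trans-illumination with weakly divergent light; each object point is
  imaged through the illumination pencil, not the full lens aperture.
  `source_model()` therefore defaults to a 5 degree divergence half-angle,
  and `find_best_focus()` minimises the rms spot radius of that pencil. For
  the default train this lands at 0.732 mm in front of the ball centre, 0.3%
  off the paraxial front focus, with a sub-pixel (~0.2 um) traced spot.
* **Numerical aperture.** `numerical_aperture()` reports the first-order
  (paraxial marginal-ray) NA: the widest paraxial cone from the on-axis
  object point that clears every aperture, found by tracing an
  infinitesimal-angle ray and scaling. For the default train the 0.4 mm
  field aperture is the stop and NA = 0.479. The real-ray acceptance is
  *larger* (~0.68, limited by total internal reflection): spherical
  aberration folds steep rays back inside the stop. Those rays carry a
  100 um-scale aberration halo rather than image-forming light, which is why
  the conventional quoted NA is the first-order one.
* **Depth of field.** Because the full-aperture traced spot never comes
  close to one pixel, a criterion "traced rms <= pixel pitch" has no
  solution. `system_metrics()` instead reports the sensor-referred geometric
  pixel-blur depth of field $2\sqrt{2}\,p/(M\,\mathrm{NA})$ — the axial
  object range over which the first-order defocus blur (a disc of radius
  $M\,\mathrm{NA}\,\Delta z$ on the sensor, Gaussian-equivalent rms
  $R/\sqrt 2$) contributes no more than one pixel pitch $p$ of rms spot
  growth — alongside the diffraction estimate $\lambda/\mathrm{NA}^2$. For
  the default train these are 2.83 um and 2.40 um at 550 nm; both estimates
  agree to within a micron, which is the honest statement of this quantity's
  precision.

Magnification is computed two ways (the chief ray aimed through the stop
centre, and the centroid of the imaging pencil; they agree to ~1% here), and
the field of view is the smaller of the sensor-limited extent and the
vignetting-limited field (where pencil throughput falls below 50%).
`usaf_frequency()` implements the resolution-chart rule
$2^{g + (e-1)/6}$ lp/mm.

```{r metrics, eval = FALSE}
system_metrics(build_iphone2g_microscope(), wavelength_nm = 550)
```

# Multifocus fusion

The focus measure is the sum-modified Laplacian: absolute discrete second
differences in x and y, summed over a window (default 3 x 3, step 1,
reflective borders). Fusion decomposes each co-registered frame with a
multiscale transform, takes every coefficient from the frame with the
locally largest SML of the coefficient plane, smooths each per-band decision
map with a single-pass 3 x 3 majority vote (ties to the lowest frame index),
and inverse-transforms, clipping to the input intensity envelope.

The transform is pluggable: the default is a separable Haar wavelet
(orthonormal, exact reconstruction, implemented in the package, with
reflective padding to a multiple of $2^{levels}$), and a Laplacian pyramid
is available. Directional multiscale bases can squeeze out slightly better
seam behaviour, but the operative mechanism — per-coefficient max-SML
selection with a consistency vote — lives in the fusion rule, not the basis,
and the Haar basis keeps reconstruction exact and dependencies at zero.
Fusion operates on grayscale; the CLI reduces RGB inputs to luminance.

`usable_fov()` quantifies restoration: the SML map is aggregated into
16 px blocks and the largest centred square in which every block reaches a
fraction (default 50%) of the peak block is reported. The all-blocks rule is
deliberately strict — one soft block ends the square — which is why the
fusion protocol below uses a spatially uniform texture.

# Radial distortion

`fit_pincushion()` fits $r_d = r_i\,(1 + k_1\tilde r^2 + k_2\tilde r^4)$
(normalised radius $\tilde r = r_i / r_\mathrm{norm}$, so $k_1$ is
scale-free; positive = pincushion) together with the distortion centre:
coefficients are linear least squares at fixed centre, the centre is a
Nelder-Mead outer loop. Collinear or field-concentrated correspondence sets
are rejected. `undistort()` resamples the ideal image by evaluating the
forward model at every output pixel (bilinear interpolation); `distort()`
(used by the generators) inverts the radial polynomial by Newton iteration,
accurate to well under 0.05 px across the domain.

# Spectrometer model

`diffraction_angle()` solves the grating equation
$\sin\theta_i + \sin\theta_m = m\lambda/d$. The tube is treated as defining
normal incidence on the grating ($\theta_i = 0$ by default, configurable):
the 45-degree cut of the physical tube is taken as mechanical convenience
for pointing the camera, not as a grating tilt — a stated modelling risk,
but one that reproduces the instrument's measured ~10 nm resolution at
first order.

The two slits of widths $w_1, w_2$ over tube length $L$ give an angular
acceptance equal to the convolution of two rect functions — a triangle for
equal slits — with FWHM $\max(w_1, w_2)/L$; through the local dispersion
this becomes $\Delta\lambda = d\cos\theta_m\,\Delta\theta$, i.e. 10.8 nm at
546 nm for the 1 mm / 77.5 mm geometry, scaling linearly with slit width
(5.4 nm at half-millimetre slits). `extract_spectrum()` averages ROI rows
(0-based, half-open ROIs; RGB handled by channel sum by default — traces are
relative, as no sensor QE correction is attempted), with optional background
row subtraction. `calibrate_wavelength()` fits a degree-1 or -2 pixel-to-nm
polynomial through lamp-line peaks (order-invariant pairing, monotonicity
enforced over the valid range), and `fwhm()` measures line widths by linear
interpolation at half of the baseline-subtracted peak. `transmission_ratio()`
divides spectra on the reference grid, masking wavelengths where the
reference falls below a noise floor. The fixture line list
(`lamp_lines()`: 405, 436, 546, 611 nm) is the standard set of strong
fluorescent-lamp lines.

# Cell counting

`count_smear()` chains three steps. `correct_background()` removes
large-scale illumination (grayscale morphological closing with a 61 px disc
for dark cells — reflect-padded so borders are unbiased — or a robust
quadratic surface fit restricted to likely-background pixels); output is
mean-preserving, so contrast polarity never flips. `segment_cells()`
thresholds with Otsu after light Gaussian smoothing, fills the holes left by
central pallor, opens with a small element, and splits touching cells by a
watershed of the foreground distance transform whose markers are
distance-map maxima deeper than 10% of the maximum (the `h_maxima_depth`
parameter: larger = fewer splits). `count_cells()` filters regions to the
20-150 um^2 band — a projected red cell is ~50 um^2, platelet-scale debris
falls below — and emits per-cell morphometrics (centroid, area,
eccentricity, mean intensity). Counts are invariant to global intensity
scaling and 90-degree rotation. Cell-class discrimination is out of scope;
the morphometrics are emitted for downstream use.

# Synthetic fixtures and what they do (not) show

All generators are pure functions of their parameters and a seed
(byte-identical reruns), and each returns the exact ground truth needed to
score the downstream module.

* `make_ronchi()` / `make_three_bar_target()`: binary rulings and
  5:1-aspect three-bar elements at exact object-plane frequencies.
* `make_blood_smear()`: absorbing cells with an annulus profile (central
  pallor), default 115 cells of radius 3.8 +/- 0.3 um at 0.46 um/px on a
  600 x 600 canvas, 10% of cells as pairs overlapping by ~30% of a radius,
  15 platelet-scale specks, a 15% illumination ramp, Poisson shot noise
  (200 photons at unit intensity) plus Gaussian read noise, quantised to
  8 bits last. These are the standard smear conditions used by the counting
  protocol (20 seeds).
* `apply_aberrations()`: per-pixel Gaussian blur with
  $\sigma(r) = b\,\lvert r^2/2R - \Delta z\rvert$, field-curvature radius
  $R = 1.1$ mm (the Petzval-scale value $n f$ for the default ball) and
  $b = \mathrm{NA}/(\sqrt 2\, s)$ px/um (the rms-matched disc-to-Gaussian
  conversion at NA 0.479 and object-plane pixel $s = 0.458$ um), then the
  optional radial warp. Variable blur is realised by blending a bank of
  nine uniformly blurred copies, linearly in sigma.
* `make_texture_scene()`: the fusion-protocol scene — a crossed sinusoidal
  grating of 6 px period with seed-randomised phase (deterministic local
  contrast, so block SML responds to blur only), or a speckle random field
  for generic texture.
* `render_spectral_image()`: each line is the closed-form convolution of
  the triangular slit acceptance with a Gaussian intrinsic width placed at
  its mapped pixel; an optional Planck continuum is added with the mapping
  Jacobian; dark row margins remain for background subtraction.

What passing these protocols shows is that the algorithms are correct on
images whose degradations (defocus growing as $r^2/2R$, smooth illumination
gradients, Poisson/Gaussian noise, 8-bit quantisation) match the physical
model of the instrument. What they do not show: robustness to stain
variability, debris and white cells in real smears; to camera autoscaling
and demosaicing artifacts; to stray light and second-order overlap in real
spectra; or to misregistration between focal frames (frames are assumed
co-registered; only translation-level alignment would be needed and is out
of scope here).

# Numerical choices and problem sizes

Best focus is a golden-section search to 0.1 um; ray fans use 25 rings x 8
azimuths (201 rays) for metrics. SML ties break to the lowest frame index.
The distortion centre search runs Nelder-Mead to `reltol` 1e-12; Newton
inversion of the radial map runs 25 iterations. Peak finding refines
positions by three-point parabolic interpolation (needed to reach < 0.2 nm
calibration residuals at ~0.5 nm/px dispersion). Degenerate inputs error
early: empty trains, windows larger than images, non-monotonic calibrations,
evanescent diffraction orders, collinear correspondence sets; an empty
foreground mask yields zero labels rather than an error.

The shipped protocols use 512 x 512 fusion scenes over 10 seeds and
600 x 600 smears over 20 seeds — sizes chosen so the full suite exercises
every pipeline end-to-end in well under a minute each while leaving the
statistics (median over seeds) stable.

# Known limitations

Single-wavelength tracing only (no chromatic aberration); the phone lens is
an ideal thin lens (its real aspheric is unpublished); polarisation is not
modelled. The spectrometer bandwidth depends on an unspecified
grating-to-sensor standoff and is not predicted. The fusion usable-FOV
metric is texture-dependent by design and should be read as a relative,
protocol-defined quantity, not an absolute field size.
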