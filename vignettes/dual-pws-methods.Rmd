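---
title: "Interference imaging of nanoscale structure and dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interference imaging of nanoscale structure and dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipws)
```

## The measurement model

Partial wave spectroscopy (PWS) microscopy interferes light backscattered by
sub-diffraction refractive-index fluctuations inside a sample with a strong
reflection from the substrate-sample interface (the *reference arm*). The
reference acts as an interferometric local oscillator: a scatterer far too
small to image directly still modulates the detected intensity measurably,
because its weak field is read out against the strong reference
(heterodyne amplification). The detected reflectance at a pixel is

$$I = \left| \sqrt{R_\mathrm{ref}} + \textstyle\sum_j w_j\, a_j\,
e^{i(2 k z_j + \phi_j)} \right|^2 ,$$

where $R_\mathrm{ref}$ is the Fresnel reflectance of the interface, $a_j$ the
scattering amplitude of particle $j$, $w_j$ its lateral point-spread weight
at the pixel, $z_j$ its depth, and $k = 2\pi n/\lambda$ the wavenumber in the
medium. The factor $2k$ is the backscattering phase rate: light travels the
depth twice.

Two acquisition modes probe two aspects of the sample:

* **Spectral cubes** $I(\lambda, x, y)$, acquired over 500-700 nm, capture
  how the interference oscillates with wavelength. A scatterer at depth $z$
  contributes an oscillation of period $\pi/(nz)$ in vacuum wavenumber, so
  the per-pixel spectral standard deviation $\Sigma_s$
  ([`compute_sigma_s()`]) summarises nanoscale structural heterogeneity.
* **Temporal cubes** $I(t, x, y)$, acquired at one wavelength, capture how
  the interference fluctuates as scatterers move.

From the temporal fluctuations $\delta I = I - \bar I$ the package extracts:

* the variance $\Sigma_t^2 = \frac{1}{\Delta T}\int \delta I^2\,dt$,
  proportional to the **fractional moving mass** $m_f = m_c \Phi$ (mass of
  the typical moving cluster times the volume fraction of mobile mass);
* the temporal autocorrelation $B_{\delta I}(\tau)$, which for diffusive
  motion decays as $e^{-\tau/t_c} = e^{-4k^2 D \tau}$, so the **diffusion
  coefficient** is $D = 1/(4 k^2 t_c)$.

For isochronic motion $\Sigma_t^2$ is insensitive to the *speed* of the
moving material, while the ACF decay measures only the speed -- the two
quantities are complementary.

### Wavenumber convention

The relation $D = -\mathrm{decay}/(4k^2)$ scales as $1/k^2$, so the $k$
convention matters quantitatively. This package uses the **medium**
wavenumber $k = 2\pi n_\mathrm{medium}/\lambda_\mathrm{vacuum}$ (the
physically correct phase rate for backscattering inside the sample) with
$n_\mathrm{medium}$ a required metadata field, and every estimator writes
the convention string into its provenance.

## The 11-step diffusion analysis

`estimate_D_mean()` implements the whole-field analysis chain:

1. normalize the raw cube for LED intensity, exposure time, and dark counts
   (`normalize_cube()`; `estimate_led_reference()` provides a per-frame LED
   reference from the spatial mean of the reference-dominated field);
2. subtract the temporal mean per pixel;
3. compute the per-pixel autocorrelation (biased, $1/N$, FFT-based --
   the standard dynamic-light-scattering estimator, stable at large lags);
4. discard low-SNR pixels whose lag-0 ACF is below $\sqrt 2$ times the
   background lag-0 ACF (`snr_filter()`);
5. subtract the spatial-mean ACF of an empty-field background cube
   (`background_acf()`) from each pixel's ACF;
6. average the ACFs across the retained pixels and normalize the mean ACF to
   one at lag zero;
7. truncate the mean ACF at its first non-positive value, keeping the lag
   spacing uniform for the logarithm;
8. take the natural log of the mean ACF;
9. (map variant only, `estimate_D_map()`) smooth each lag plane of the ACF
   stack with a Gaussian filter, default $\sigma = 2$ px, before the
   per-pixel normalization and slope;
10. take the slope of the log mean ACF between two lags;
11. convert to $D = -\mathrm{decay}/(4k^2)$.

Two numerical choices in this chain deserve explanation, because both are
places where the obvious implementation is measurably biased on simulated
ground truth.

**Slope lags.** The camera integrates intensity over each exposure window.
For a fluctuation with exponential ACF (rate $\gamma$) sampled with
contiguous exposures of length $\Delta$, the integrated signal's
autocovariance is

$$C_0 = \tfrac{2\sigma^2}{\gamma^2}(\gamma\Delta - 1 + e^{-\gamma\Delta}),
\qquad
C_m = \tfrac{\sigma^2}{\gamma^2}\,(1 - e^{-\gamma\Delta})^2\,
e^{-\gamma\Delta(m-1)} \quad (m \ge 1).$$

The lag-0 point is distorted (and additionally carries all the white shot
and read noise), but from lag 1 onward the sequence is *exactly* geometric
with the true rate: $C_{m+1}/C_m = e^{-\gamma\Delta}$. A slope taken between
lag 0 and lag 1 therefore underestimates $\gamma$ severely when the exposure
is comparable to $t_c$ (which it is at the phantom settings: 32 ms exposure
against correlation times of 22-90 ms), while a slope between lags 1 and 2
needs no exposure correction at all. The default is `slope_lags = c(1, 2)`;
`c(0, 1)` is available for comparison.

**Pixel aggregation.** Averaging the *logarithm* of per-pixel ACFs (a
geometric mean across pixels) is attractive for exponential decays, but the
log of a noisy, nearly-zero ACF value is strongly biased, and the
positivity truncation then selects pixels with favourably noisy lags. Dim
pixels dominate this bias. The whole-field estimator instead averages the
background-subtracted ACFs across pixels arithmetically -- which weights
pixels by their fluctuation power -- and takes the log of the mean ACF. On
simulated phantoms this removes a systematic overestimate of $D$ that grows
with $t_c$. The per-pixel map variant cannot average across the field; it
uses the spatial Gaussian smoothing of step 9 instead.

**Exposure correction.** Finite exposure attenuates the *measured variance*
by the boxcar factor $f(x) = 2x^{-2}(x - 1 + e^{-x})$ with
$x = \mathrm{exposure}/t_c$ (`exposure_attenuation()`). The correction
(dividing by $f$) is applied when comparing $\Sigma_t$ to theory, using the
theoretical $t_c$ of each phantom condition; it is *not* applied to
diffusion estimates, which with the lag 1-2 slope do not need it. Variance
lost to integration can be divided back out; decay rates cannot be
"un-integrated", they simply must be read off lags where integration is
harmless.

**Negative values and clamping.** Reference subtraction can push a
per-pixel $\Sigma_t^2$ below zero when the pixel holds no signal; such
pixels are clamped to zero and masked invalid. Because clamping alone would
bias a field average upward, the unclamped spatial mean is kept in the map
provenance and used for whole-field summaries. ACF truncation is a
truncation at the first non-positive lag of the *mean* ACF, not pointwise
deletion, so lag spacing stays uniform.

### Sensitivity range

`sensitivity_range()` brackets the resolvable diffusion coefficients by
requiring the correlation time to fit between the exposure (faster motion is
averaged away within one frame) and the acquisition time (slower motion
never decorrelates): $D_\mathrm{max} = 1/(4k^2 E)$,
$D_\mathrm{min} = 1/(4k^2 \Delta T)$. This is a deliberately simple
bracketing convention and is recorded as such in the output; sharper bounds
would need an SNR model of the full instrument, which is out of scope.
Conditions far outside this range (e.g. the 0.3% spheres in 70% glycerol,
whose $t_c$ is an order of magnitude below the exposure) cannot yield
accurate $D$; their variance remains usable after exposure correction, which
is exactly how the validation treats them.

## The phantom simulator

`make_phantom_suite()` generates the synthetic stand-in for nanosphere
phantom experiments: polystyrene spheres (RI 1.60) of radius 25-100 nm at
volume fractions 0.1-0.3% suspended in glycerol-water, imaged against a
sapphire interface. Defaults follow the phantom acquisition: 32 ms exposure,
contiguous frames, 201 frames (6.432 s), 550 nm, illumination NA 0.55,
collection NA 1.4. Ground truth for every cube (true $D$ from
Stokes-Einstein, analytic $\Sigma_t^2$, seeds, geometry) is emitted in a
manifest.

Model components and the reasoning behind them:

* **Scalar first-Born field.** Radii of 25-100 nm are far below the
  wavelength, so each sphere scatters in the Rayleigh regime with amplitude
  $a \propto r^3 (n_s^2 - n_m^2)/(n_s^2 + 2 n_m^2)$ (Clausius-Mossotti).
  No multiple scattering, no vectorial effects.
* **Brownian dynamics.** Independent Gaussian steps of per-axis variance
  $2D\,dt$, with $D$ from Stokes-Einstein at the tabulated glycerol
  viscosities (90%: 0.219 Pa s; 70%: 0.0227 Pa s at 25 C -- standard
  glycerine tables; the mixtures' refractive indices are 1.46 and 1.44).
  Depth is confined to a layer above the interface by reflecting walls;
  laterally the box (field of view plus a 0.5 um margin) wraps periodically,
  keeping the density uniform.
* **Lateral point-spread function.** Gaussian with
  $\sigma = 0.21\,\lambda/\mathrm{NA}$, integrated over the pixel area
  (error-function weights). The axial extent is a configurable depth window
  (default 1.5 um), not a focal profile.
* **Finite-exposure integration.** Intensity (not field) is averaged over
  substeps inside the exposure window; the substep count adapts to
  $t_c$ (at least 10 per frame, up to 24 for fast conditions) so that fast
  decorrelation is integrated finely.
* **Detection noise.** Poisson shot noise at a photon budget per pixel per
  frame, Gaussian read noise, and a multiplicative common-mode LED drift
  (AR(1), default 0.1% RMS, 1 s correlation time). The measurement chain
  never sees the drift directly; it removes it with the step-1 LED
  normalization, which is why that step exists.

The photon budget of the real phantom experiments is not known; the default
(2e8 photons per pixel per frame at unit reflectance, i.e. about 2e6 at the
reference reflectance) was calibrated once so that the weakest condition
(25 nm spheres at 0.1%) sits comfortably above the noise floor, and is
recorded in every cube's provenance.

**What the simulator does not emulate:** Mie/vectorial scattering,
aberrations and focal-plane structure, camera gain nonlinearity or EM
multiplication noise, sample drift, and of course real chromatin (whose
mass-density correlations are not monodisperse spheres). Passing the
phantom-recovery suite therefore demonstrates that the estimator chain is
unbiased *for the forward model it claims to invert*, under realistic noise
-- not that any biological number is reproduced.

### The analytic variance

For validation, the expected per-pixel variance of the rendered fluctuations
is computed in closed form (`analytic_sigma_t2()`): each mobile scatterer
contributes $2 R_\mathrm{ref} a^2 w^2$ (the phase-averaged square of the
interference cross term), summed over the uniform scatterer density with the
pixel-integrated PSF profile evaluated by quadrature. Exposure-corrected
measured $\Sigma_t^2$ is regressed against this quantity across conditions;
the comparison spans a ~300-fold range of variances, because amplitude
scales as $r^6$ per scatterer but density as $\Phi/r^3$, making total
variance $\propto \Phi\, m_c \propto \Phi r^3$ -- the fractional-moving-mass
proportionality the variance channel is designed to measure.

## Paroxysm timing

A cellular paroxysm is a near-instantaneous, cell-wide burst of
macromolecular motion; in a temporal cube it appears as an abrupt step in
the per-pixel fluctuation amplitude (and usually the baseline). To time it
at single-frame resolution, `detect_changepoint()` scans every split of the
trace under a Gaussian segment model in which both mean and variance may
jump, with cost $\sum_\mathrm{seg} n\,\log \hat\sigma^2$, and accepts the
best split only when it beats the no-change model by a BIC-style penalty
$c \ln n$ ($c = 3$ by default: three extra parameters). The penalty default
was chosen from the detector's operating characteristics on stationary
Gaussian noise (holding false detections below about 5% on 201-frame
traces) while keeping median timing error within one frame for variance
steps of 3x the baseline SD; both properties are asserted by the test
suite. Pixels are processed independently -- per-pixel maps, no spatial
regularisation.

`onset_histogram()` reports event fractions per frame offset from the
earliest onset (first-onset-referenced, matching how such timing histograms
are read), and `synchrony_report()` measures the maximum pairwise distance
among first-frame pixels together with the diffusion coefficient
$D = L^2/(2 d\, t)$ a molecular regulator would need to span that distance
within one frame. The mean-squared-displacement dimensionality $d$ defaults
to 2 (planar) and is recorded in every report, since such speed bounds are
convention-dependent; the classic example -- 30 um within one 35 ms frame --
exceeds 3500 um^2/s under every convention $d \in \{1,2,3\}$.

## Problem sizes and runtime

The validation suites are simulated at 32 x 32 pixels with 201 frames,
4 radii x 2 volume-fraction/viscosity arms x 5 seeds; at this size the full
validation completes in minutes on a single core while leaving hundreds of
scatterers in even the sparsest condition. The oracle checks use smaller
cubes (8 x 8) where an exhaustive loop-based recomputation is feasible, and
long synthetic acquisitions (1000-3000 frames) where an estimator is being
compared against an asymptotic closed form. Cube sizes only change
statistical precision, not any estimator's definition.

## Known limitations

* $m_f$ is reported in normalized units: the proportionality constant
  linking $\Sigma_t^2$ to physical mass depends on instrument calibration
  and is exposed as `calibration_constant` (default 1) rather than claimed.
* The two-point slope assumes a single-exponential ACF; anomalous diffusion
  or multi-component mixtures are summarised by an effective rate, and no
  multi-exponential fitting is attempted.
* The sensitivity-range bracketing is a convention, not an SNR-derived
  bound.
* `Sigma_s` is computed as the detrended spectral standard deviation; its
  inversion to physical chromatin packing parameters is out of scope, and
  no bit-compatibility with any particular instrument software is claimed
  (the detrend mode is explicit provenance for this reason).
* TIFF export quantizes to 32-bit integers with a recorded scale (one part
  in $2^{31}$); the `.rds` format is bit-exact.
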