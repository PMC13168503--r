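---
title: "Methods: four-polarization 3D orientation and localization microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-polarization 3D orientation and localization microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fourpolar)
```

## The measurement principle

A fluorophore behaves as an oscillating electric dipole. Within one camera
exposure it wobbles inside a cone, so the image encodes only the
*time-averaged second-order moments* of its transient direction
$\boldsymbol\mu$:

$$ m_{ij} = \langle \mu_i \mu_j \rangle, \qquad
   \mathbf m = (m_{xx}, m_{yy}, m_{zz}, m_{xy})^{\mathsf T}. $$

Under the wobble-cone model — the mean direction
$\mathbf u(\eta,\xi)$ with polar angle $\eta$ (0° = vertical/off-plane,
90° = in the sample plane), azimuth $\xi$ (mod 180°), and uniform
solid-angle wobbling inside a cone of *full* apex angle $\delta$ —

$$ \mathbf m(\Omega) = \gamma(\delta)\, \mathbf u \mathbf u^{\mathsf T}
   + \tfrac{1-\gamma(\delta)}{3}\,\mathbb 1, \qquad
   \gamma(\delta) = \tfrac{c(1+c)}{2},\; c=\cos(\delta/2). $$

`gamma_delta()` implements $\gamma$; its derivation (uniform density over the
spherical cap, axial cone-frame moment $(1+c+c^2)/3$) is checked in the test
suite against a Monte-Carlo average over $10^6$ directions.

The instrument splits the emission 50/50 into two arms whose pupil-plane
diaphragms select numerical apertures $\mathrm{NA}_\text{low}$ and
$\mathrm{NA}_\text{high}$; each arm is then split by a Wollaston prism into
two orthogonal linear polarizations (a half-wave plate rotates the second arm
by 45°, so the four channels analyze 0°, 90°, 45° and 135°). The four
integrated intensities are linear in the accessible moments,

$$ \mathbf I = (I_0, I_{90}, I_{45}, I_{135})^{\mathsf T}
   = \langle \mathbf K \rangle\, \mathbf m , $$

and the cross moments $m_{xz}, m_{yz}$ are invisible because their basis
images are odd over the centered circular apertures (their integrals vanish;
asserted to $10^{-6}$ relative in the tests). Orientation retrieval is the
inversion chain $\mathbf I \to \mathbf m \to \Omega=(\eta,\xi,\delta)$:
$\hat{\mathbf m} = \langle\mathbf K\rangle^{-1}\mathbf I$ (trace-normalized
and projected into the physical set), then

$$ \hat\xi = \tfrac12\operatorname{atan2}(2m_{xy},\, m_{xx}-m_{yy}), \quad
   a = \sqrt{(m_{xx}-m_{yy})^2 + 4m_{xy}^2}, \quad
   \hat\gamma = \tfrac{3(a+m_{zz})-1}{2}, $$
$$ \hat\eta = \arcsin\sqrt{a/\hat\gamma}, \qquad
   \hat\delta = 2\arccos\!\Big(\tfrac{-1+\sqrt{1+8\hat\gamma}}{2}\Big). $$

The chain is exact on noise-free data (unbiasedness to $<0.01^\circ$ is a
test), and the ratios $P_0 = (I_0-I_{90})/(I_0+I_{90})$,
$P_{45}=(I_{45}-I_{135})/(I_{45}+I_{135})$ and
$R_{\mathrm{NA}}=(I_0+I_{90})/(I_{45}+I_{135})$ expose the mechanism:
$P_0, P_{45}$ carry $\xi$ and the degree of orientational order, while the
NA filtering makes $R_{\mathrm{NA}}$ monotone in $\eta$ (vertical dipoles
radiate into larger angles, which only the high-NA arm accepts).

## The vectorial forward model

`build_pupil_field()` computes the back-focal-plane field of a dipole at
height $z_0$ in the sample medium ($n_0 = 1.33$) above the coverslip
($n_1 = 1.515$), collected by an aplanatic objective:

* angular-spectrum decomposition of the dipole field with Fresnel p/s
  transmission at the planar interface, analytically continued above the
  critical angle (this carries the supercritical-angle fluorescence, which is
  strong for emitters near the interface);
* far-field radiometric factor $n_1^{3/2}\cos\theta_1/(n_0^{3/2}\cos\theta_0)$
  and aplanatic apodization $1/\sqrt{\cos\theta_1}$, so pupil-integrated
  power equals angular power;
* height/defocus phases $e^{ik(n_0 z_0\cos\theta_0 + n_1 z_1\cos\theta_1)}$.

During development the model was validated by energy conservation: the
angular integrals over both half-spaces agree with the classical plane-wave
total-dissipated-power integral to better than 0.5% at $z_0 = 0$, 50 and
200 nm, and the supercritical share of the glass-side emission at $z_0=0$
(48%) matches the known behaviour of interface emitters. The test suite keeps
an independent cross-check: the integrated matrix
$\langle\mathbf K\rangle$ from the 2D pupil grid must agree with a 1D radial
quadrature using closed-form azimuthal integrals to <0.5% per entry.

`psf_bank()` turns the pupil fields into rendering machinery: per channel,
the analyzer-projected image amplitudes of the three dipole axes are
Fourier-transformed onto a grid oversampled 8x relative to the 130 nm pixel,
their pairwise products form the six basis images $B_{cj}(\mathbf r)$, and
area-binned copies are pre-computed for all 64 sub-pixel phases. A rendered
molecule is then a 4-term linear combination per channel — microseconds per
molecule. Rendered positions are quantized to pixel/8 = 16.25 nm and ground
truth tables always report the *rendered* position (the binning windows are
centered on pixel centers; an early uncentered version produced a systematic
8 nm bias, which is why the placement is covered by a centroid test).
$\langle\mathbf K\rangle$ itself is computed in the pupil plane (Parseval),
i.e. it is the *full-plane* image integral with no window truncation; the
finite 15-pixel rendering window carries 75–95% of each basis integral
depending on the component, which is one of the two reasons a measured
calibration matters (below).

**Photon bookkeeping.** A molecule's budget $N$ is defined *before the
split and the NA reductions*: $N$ is what the open objective
($\mathrm{NA}=1.45$) would collect from that molecule. Rendered channel
intensities are $N\,\mathbf K\mathbf m/(\mathbf q\cdot\mathbf m)$ where
$\mathbf q$ holds the full-aperture integrals; at the defaults an isotropic
emitter delivers ~40% of $N$ into the four channels (two 50/50 halves times
the NA-cut fractions).

## Calibration

`calibrate_K()` implements the rotating-polarizer protocol: a polarizer at
angle $t$ in front of an unpolarized nanobead emulates an in-plane dipole
with moments $(\cos^2 t, \sin^2 t, 0, \sin t\cos t)$, so each channel traces
$a + b\cos 2(t - t_c)$; the mean and the two quadratures identify the
$xx/yy/xy$ columns, and the bead *without* the polarizer (isotropic moments)
identifies the $zz$ column as $3I_\text{unpol} - K_{xx} - K_{yy}$. Omitting
the unpolarized frame makes $zz$ unidentifiable and raises an error. Relative
channel gains land in the rows of $\mathbf K$ and cancel in retrieval (a
tested invariance).

`calibrate_K_estimator()` runs this protocol *through the chosen intensity
estimator* on noise-free renders. This matters: a symmetric-Gaussian fit
recovers ~80% of a low-NA channel's photons but only ~74% of a high-NA
channel's (different PSF shapes and tails), which, uncorrected, biases
$\hat\eta$ by over +10°. The estimator-matched matrix absorbs this exactly
as the real instrument's bead calibration absorbs its channel gains. Each
calibration state is rendered at a photon count proportional to
$\mathbf q\cdot\mathbf m$ — a constant-brightness source, which keeps the
measured series exactly linear in $\mathbf m$.

`estimator_response()` maps the residual, orientation-dependent recovery
factor $g_c(\eta,\xi,\delta)$ on a grid (the in-plane + isotropic
calibration states cannot probe every PSF shape; the Gaussian-fit total
recovery still varies from +8% at $\eta=0$ to −1% at $\eta=90°$ relative to
the calibrated model). The known-brightness retrieval interpolates this
surface to de-bias its forward model.

## Localization pipeline

Per frame and channel: a GLRT compares a fixed-radius Gaussian peak plus
offset against offset-only in an 11×11 window under Gaussian noise (the
statistic $N\log(SS_0/SS_1)$ is thresholded at the $\chi^2_1$ quantile of
the false-alarm probability, default $10^{-3}$; empirical null calibration
is a test). The fixed detection radius is the Gaussian-equivalent radius of
the isotropic-emitter PSF predicted by the forward model (~1.1 px at the
defaults). Detections are then fitted with one of four estimators —
free-radius symmetric Gaussian, rotated elliptical Gaussian, fixed-radius
symmetric Gaussian, or background-subtracted box sum with centroid — and the
four channels are associated by mutual nearest neighbour within 3x the
combined position CRLB. Fused positions are intensity-weighted means.

Estimator trade-offs, measured on this model: the free-radius fit's
radius–volume covariance inflates intensity noise by ~1.5x; the box sum is
exactly linear (no shape bias) but pays dearly for its annulus background
estimate at 10 photons/pixel; the fixed-radius fit is the best compromise
for moment inversion and is the default of the validation wrappers. The
free-radius fit remains the default of `run_pipeline()` because downstream
analyses need the fitted PSF radius (the focus classification).

## Orientation retrieval variants

With four intensities and four unknowns $(\eta,\xi,\delta,\text{brightness})$
the scale-free inversion is *exactly determined*: any weighting reproduces
the analytic chain wherever the data are feasible. Its precision is set by
the model's conditioning, and the polar angle inherits an upward fold bias
at low $\eta$ (the in-plane amplitude $a$ is non-negative). Two refinements
are provided:

* `orientation_wls()` — weighted least squares with the brightness profiled
  out; useful only for off-manifold (clipped) records.
* `orientation_ml()` — *known-brightness* Poisson maximum likelihood. When
  $N$ is known (a simulation at fixed budget, or an absolutely calibrated
  source) the intensities over-determine the three angles and the overall
  collection efficiency, which varies by ~40% between vertical and in-plane
  molecules, becomes an additional $\eta$ signal. This estimator reaches the
  three-parameter Cramér–Rao bound (within 1.5x, a test) and is what the
  Monte-Carlo validation uses, with the response surface above.

## Cramér–Rao bounds

`crlb_orientation()` computes the Fisher information of $(\eta,\xi,\delta)$
from the four integrated intensities under Poisson noise with additive
background, with analytic moment derivatives (finite-difference-validated):
$F_{ij} = \sum_c \partial_i I_c\, \partial_j I_c /(I_c + B_c)$, bounds in
degrees. $B_c$ is the background variance the intensity estimate actually
carries. The default is the matched-estimator effective area
$4\pi\sigma_c^2$ pixels (~150 photons/channel at 10/px): a PSF-weighted
least-squares amplitude estimate over uniform background has exactly this
variance contribution. Aggregating instead over the full 11×11 estimation
window (the `"window"` option, $B_c = 1210$) raises the minimal wobble bound
from ~8.5° to ~15° at the reference settings (5000 photons,
$\mathrm{NA}_\text{low}=1.04$, $\mathrm{NA}_\text{high}=1.3$); only the
effective-area reading is compatible with a sub-10° wobble floor, which is
why it is the default. Both variants stay available and the sensitivity is
this paragraph.

At those settings the bounds reproduce the method's known behaviour: a few
degrees for $\eta,\xi$ at mid-range, degradation towards $\eta \to 0°, 90°$
and $\delta \to 180°$ (where $\xi$ is ill-defined and the bound diverges),
$1/\sqrt N$ scaling, and gain invariance.

## The synthetic-data generators and what they do (not) emulate

`make_scene_random_orientations()` reproduces the validation conditions:
positions uniform with ≥8 px separation (6 px edge margin so fitting windows
fit), mean directions area-uniform on the upper hemisphere, fixed wobble,
fixed photon budget; defaults are 10 molecules per 64×64-px frame, 5000
photons, 10 background photons/pixel/channel. `make_scene_sphere_membrane()`
places normal-anchored labels on horizontal circles of a sphere (polar angle
grows from bottom to equator, azimuth radial); `make_scene_filaments()`
anchors labels at a fixed offset angle (default 20°) from 3D line segments
with random azimuth about the axis. `render_stack()` adds background,
Poisson shot noise, optional Gaussian read noise and optional pupil
aberrations (Noll-indexed Zernike phases, applied identically to both arms),
and tiles the four channels as camera quadrants.

Not emulated, hence untested against real data: blinking kinetics and
duty cycles, EMCCD excess noise, polarization-dependent aberrations of real
dichroics (only scalar gains are absorbed by calibration), spatially varying
calibration, axially extended structures beyond the emitter-height
parameter, and molecular brightness heterogeneity (the known-brightness
retrieval exists precisely because the validation uses a fixed budget; on
real data the scale-free chain is the honest default).

## Numerical choices

* Pupil grid 256×256 over the objective NA (tests use 160; the K-matrix
  quadrature error stays below 0.5%); rendering oversampling 8x, 15-px
  patches, 64 pre-binned sub-pixel phases.
* Gauss–Newton fits are Levenberg-damped with analytic Jacobians, 50
  iterations maximum; radii are bounded to the optically plausible range
  (0.3–4 px) and the sub-pixel center is constrained to ±2.5 px of the
  integer-pixel detection, reflecting the two-stage detect-then-refine
  design (without these, rare fits on nearly dark cross-polarized channels
  wander onto background). Non-converged fits fall back to the box estimator
  and are flagged. The rotated-Gaussian start is made slightly anisotropic
  because the angle is degenerate at $\sigma_x=\sigma_y$.
* The ML refinement uses two bounded BFGS starts (the analytic inversion and
  one alternate across the 45° ridge).
* Degenerate retrievals are flagged (`ill_defined`, `clipped`, `refined`),
  never dropped; dropping is the job of `filter_confidence()` (polar angle
  strictly inside (5°, 88°), wobble inside (5°, 175°), >1000 detected
  photons).
* Ties at population-bin edges go to the lower bin; radial distance bins are
  half-open `[k·step, (k+1)·step)`; stick maps fold the azimuth with the
  180° line symmetry.
* Scene randomness uses R's generator under an explicitly recorded seed with
  caller state restored.

## Validation problem sizes

The acceptance computations simulate 10,000 molecules (1000 frames of 10)
for the population-misclassification statistics; the localization
Monte-Carlo uses a 36-point orientation grid with 60 repeats per point and
estimator; the CRLB floor is evaluated on a 2°-spaced grid. These sizes give
binomial/sampling errors well below the tolerances being checked.

## Known limitations

* The wrong-bin fraction of the *off-plane* population (~10% at the
  validation conditions) is larger than for the other two populations
  because the class boundary at 30° sits where the polar-angle bound is
  ~3.3° and the hemisphere-uniform population is dense; the retrieval is
  CRLB-limited there, not estimator-limited.
* The collected-fraction of an unpolarized emitter depends strongly on its
  height: 50% of the open-objective signal at NA 1.3 for an emitter exactly
  at the interface, ~58% at the 50 nm center height of a 100 nm calibration
  nanobead (the package's unpolarized reference), approaching 87% far from
  the interface where supercritical coupling vanishes. `collection_fraction()`
  exposes the height via the configuration and both normalizations
  (objective-collected and total-emitted).
* Multi-emitter (overlapping-PSF) fitting and temporal linking are out of
  scope; dense scenes lose molecules at the pairing stage.
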