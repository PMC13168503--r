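# fourpolar

Single-molecule orientation and localization microscopy (SMOLM) with a
four-channel polarization splitter and numerical-aperture filtering — a
simulation and analysis toolbox in R.

## The problem and the method

A fluorophore is an oscillating dipole. Standard localization microscopy
reports only its position; its 3D orientation and its rotational mobility
carry structural information (e.g. how a label is anchored to an actin
filament or a membrane), but within one camera exposure only the
*time-averaged second-order moments* of the dipole direction are measurable:

    m = (m_xx, m_yy, m_zz, m_xy),    m_ij = <mu_i mu_j>.

Under the wobble-cone model — mean direction u(eta, xi) with polar angle
eta (0 deg = vertical, 90 deg = in-plane), azimuth xi (mod 180 deg), and
uniform wobbling inside a cone of full apex angle delta —

    m(Omega) = gamma(delta) u u' + (1 - gamma(delta))/3 * I,
    gamma(delta) = c(1 + c)/2,  c = cos(delta/2).

The instrument splits the emission 50/50, masks the two arms at NA_low and
NA_high in relayed pupil planes, and analyzes each arm along two orthogonal
polarizations (0/90 and, behind a half-wave plate, 45/135). The four
integrated intensities are *linear* in the accessible moments,

    I = (I0, I90, I45, I135)' = <K> m,

so orientation retrieval is a matrix inversion followed by closed-form
angle extraction — no PSF-model fitting. The polarization ratios encode xi
and the orientational order; the low/high-NA ratio encodes eta, because
tilted dipoles radiate into large angles that only the high-NA arm accepts.

The package implements the full chain: a vectorial dipole-near-interface
forward model (including supercritical-angle emission), the propagation
matrix `<K>` and rendered polarized PSFs, nanobead + rotating-polarizer
calibration, affine channel registration, GLRT spot detection, Gaussian and
box intensity estimators, channel pairing, moment inversion and orientation
retrieval (analytic, weighted, and known-brightness maximum-likelihood),
Fisher-information/Cramer-Rao bounds, Monte-Carlo scene generators
(random orientations, membrane-coated spheres, labelled filaments), drift
correction, confidence filtering, orientation-population statistics,
radiality profiles and stick-map rendering.

## Worked example

```r
library(fourpolar)
cfg  <- optical_config()            # NA 1.45 objective, arms at NA 1.1 / 1.3
bank <- psf_bank(cfg)

# simulate a validation-style stack: 10 molecules/frame, wobble 100 deg,
# 5000 photons each, 10 background photons/pixel
scene <- make_scene_random_orientations(n_molecules = 10, n_frames = 50,
                                        delta_fixed = 100, photons = 5000,
                                        seed = 1)
stack <- render_stack(scene, noise = noise_model(background = 10),
                      bank = bank, seed = 2)
stack
#> <fp_stack> 50 frame(s) of 128x128 (4 quadrants of 64 px), 500 molecules

# detect, fit, pair, invert, retrieve (known-brightness ML refinement)
tab <- run_pipeline(stack, bank, estimator = "gauss_fixed",
                    retrieval = "ml", known_photons = 5000)
dplyr::select(tab, frame, x_nm, y_nm, photons, eta, xi, delta)
#> # A tibble: 422 x 7
#>   frame  x_nm  y_nm photons   eta      xi delta
#>   <int> <dbl> <dbl>   <dbl> <dbl>   <dbl> <dbl>
#> 1     1 4953. 1180.   1348.  33.4  43.5    95.1
#> 2     1 2142. 1946.   2174.  80.3  44.0    97.0
#> 3     1 6973. 2194.   1861.  58.8   0.319  98.6
#> ...

m <- match_ground_truth(tab, stack$truth)
sprintf("matched %d/%d; position RMS %.1f nm; mean |eta error| %.1f deg",
        nrow(m), nrow(scene), sqrt(mean(m$dx_nm^2 + m$dy_nm^2)),
        mean(abs(m$eta - m$eta_true)))
#> "matched 422/500; position RMS 7.9 nm; mean |eta error| 4.0 deg"
```

(The 78 unmatched molecules are removed by the confidence filter — polar
angle outside (5, 88) degrees, wobble outside (5, 175), or under 1000
detected photons.)

Angular precision limits and the aperture trade-off:

```r
crlb_orientation(c(45, 0, 100), bank$K, N = 5000, bg_per_px = 10,
                 q = bank$q, sigma_px = bank$sigma_px)
#>   eta    xi delta
#>  3.31  3.47  9.75        # degrees, Cramer-Rao standard-deviation bounds

100 * collection_fraction(optical_config(z0 = 50), 1.3)
#> 57.9                     # % of the open-objective signal kept at NA 1.3
                           # for an unpolarized nanobead 50 nm above glass
```

Each result type has plotting helpers (`autoplot()` on CRLB maps and polar
histograms, `plot_stick_map()` / `render_stick_map()` for orientation maps)
and broom-style `tidy()`/`glance()` methods for calibrations and CRLB maps.
A thin command-line wrapper with `simulate`, `localize`, `crlb` and `render`
subcommands lives in `inst/scripts/fourpolar-cli.R`.

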