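# cassir

Coded aperture snapshot spectral imaging (CASSI) in R: forward
simulation, augmented-Lagrangian ADMM reconstruction, and resolution
metrology for a snapshot hyperspectral fundus-imaging system.

## The problem

Spectral retinal imaging needs a full (x, y, λ) datacube, but scanning
spectral cameras are too slow for a moving eye. A CASSI camera captures
the whole cube in one exposure: a binary coded mask modulates the scene, a
prism shears each wavelength laterally, and the sensor records a single
multiplexed 2D projection

    y = Φ f + g,

where `f` is the vectorized datacube, `Φ` the mask-shift-sum sensing
operator and `g` sensor noise. Recovering `f` from `y` is a compressive
inverse problem. This package is for researchers who want to prototype
and test that pipeline quantitatively without hardware: a physically
faithful, matrix-free `Φ` (forward, exact adjoint, diagonal Gram), the
reconstruction algorithm, the instrument's dispersion calibration and
USAF-1951 resolution metrology, and synthetic phantoms for every test
scene.

## The reconstruction at its core

The augmented-Lagrangian / ADMM scheme alternates three steps:

* a **denoising step** `v = prox_{Ψ/γ₂}(f − λ₂/γ₂)` — the prior Ψ is
  pluggable, with anisotropic total variation as the classical default;
* a **projection step**, the exact closed-form solution of
  `f = (γ₂I + γ₁ΦᵀΦ)⁻¹ (λ₂ + γ₂v + Φᵀ(γ₁y − λ₁))`, computed in one shot
  because `ΦΦᵀ` is exactly diagonal for a binary mask with distinct
  per-band shifts;
* **multiplier updates** `λ₁ ← λ₁ − γ₁(y − Φf)`, `λ₂ ← λ₂ − γ₂(f − v)`.

The unfolded-network variant of this algorithm (learned denoiser, trained
penalties) is out of scope; the package implements the algorithmic
skeleton with classical priors and exposes the guidance features
(`γ₂` map, shifted-mask stack, Gram diagonal) to any external denoiser.

## Worked example

```r
library(cassir)

# the packaged prism calibration and the band grid it induces
model <- cassi_dispersion()
discretize_bands(model, 445, 602, feature_px = 2)
#> <band_discretization> L = 35 bands, 445.0-600.1 nm, shifts 0..68 px (step 2)

resolution_report(model)
#> Spectral resolution by band:
#> # A tibble: 4 × 4
#>   lambda_start_nm lambda_end_nm nm_per_pixel spectral_resolution_nm
#>             <dbl>         <dbl>        <dbl>                  <dbl>
#> 1             445           480         1.67                    3.3
#> 2             480           510         2                       4
#> 3             510           560         2.5                     5
#> 4             560           602         3.33                    6.6
#> Average spectral resolution: 5 nm (exact 4.858 nm)
#> Spatial resolution: horizontal 17.5 um (group 5 element 6, 57.0 lp/mm)
#>                     vertical   15.6 um (group 6 element 1, 64.0 lp/mm)
#> Contrast threshold for resolvability: 0.40

# simulate and reconstruct a synthetic retina scene
centers <- seq(445, 602, length.out = 8)
scene <- phantom_eye(32, 32, centers, seed = 1)
mask  <- random_mask(32, 32, feature_px = 2, fill = 0.5, seed = 2)
op    <- sensing_operator(mask, seq(0, 14, by = 2))
op
#> <sensing_operator> scene 32 x 32 x 8 -> detector 32 x 46, shifts 0..14 px

y   <- cassi_forward(op, scene)
rec <- admm_reconstruct(y, op, denoiser("tv", strength = 0.1),
                        n_iters = 50, clamp_nonneg = TRUE,
                        band_centers_nm = centers)
rec
#> <cassi_reconstruction> tv prior, 50 iterations (gamma1 1, gamma2 1)
#>   final residuals: data 0.04602, splitting 0.07607

psnr(rec$cube, scene)          # voxelwise fidelity: 20.6 dB
spec <- apply(unclass(rec$cube), 3, mean)   # field-averaged spectrum
# relative error vs attr(scene, "mean_spectrum"): 0.54 %
```

The 35 bands, the 3.3–6.6 nm per-band resolutions averaging 5 nm, and the
17.5 µm / 15.6 µm spatial periods are the calibrated properties of the
instrument the package models. The reconstruction numbers show what the
classical TV prior attains at this desk scale: voxelwise recovery of a
vessel-dense scene converges near 20 dB (this is the regime the original
system addresses with a learned denoiser), while the field-averaged
spectrum — the quantity used for spectral validation — comes back well
under 1 % error. `tidy(rec)` returns the per-iteration residuals and
`autoplot(rec)` plots them.

A command-line interface wraps the same pipeline
(`inst/cli/cassi phantom | simulate | reconstruct | evaluate`); see
`cassi_main()`.

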