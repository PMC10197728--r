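---
title: "Coded aperture snapshot spectral imaging: model, reconstruction and metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coded aperture snapshot spectral imaging: model, reconstruction and metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassir)
```

## The measurement model

A CASSI camera records a spectral datacube $f(x, y; \lambda)$ in a single
exposure by multiplexing it onto a 2D sensor. Three physical stages are
modelled:

1. **Coding.** A binary mask $T(x, y)$ at a relayed image plane modulates
   every wavelength identically: $f_1 = f_0(x, y; \lambda)\, T(x, y)$.
2. **Dispersion.** A prism shears the coded image laterally by a
   wavelength-dependent shift $D(\lambda)$:
   $f_2 = f_0(x + D(\lambda), y; \lambda)\, T(x + D(\lambda), y)$.
3. **Integration.** The sensor integrates over wavelength and over each
   pixel's footprint, yielding (after discretizing the spectrum into $L$
   bands with integer per-band shifts $d_k$)
   $$Y_{mn} = \sum_{k=0}^{L-1} T_{m,n-d_k}\, f_{m,n-d_k,k} + g_{mn},$$
   or in vectorized form $y = \Phi f + g$.

`sensing_operator()` realizes $\Phi$ matrix-free: per-band shift, mask,
sum. The pixel-footprint integration is realized as discrete box sampling
on the camera grid with integer-pixel band shifts; sub-pixel splatting is
deliberately not modelled, because the system's smallest coded feature
spans a whole number (two) of camera pixels and the band grid is chosen so
shifts are integers. The detector is `max(shifts)` columns wider than the
scene, so shifted energy is never cropped and the operator conserves the
coded energy exactly.

Two structural facts carry the whole reconstruction module:

* the adjoint is again a shift-mask-crop operation
  (`cassi_adjoint()`), exact to machine precision, and
* $\Phi\Phi^T$ is **exactly diagonal** for a binary mask and per-band
  shifts — each detector pixel receives each band from exactly one scene
  column. `gram_diagonal()` returns this diagonal as a detector-shaped
  count map $R$.

The noise term $g$ is additive i.i.d. Gaussian (`add_noise()`), the
standard CASSI assumption; a Poisson model is a documented extension hook
rather than an implemented option. The operator accepts negative values
(optimization iterates need them); only the phantom constructors enforce
physical non-negativity.

## Dispersion calibration and band discretization

The prism dispersion is piecewise linear in the calibrated range: four
contiguous segments between 445 and 602 nm with powers 1.67, 2.00, 2.50
and 3.33 nm/pixel (`cassi_dispersion()`; also shipped as
`inst/extdata/dispersion_default.json`). `dispersion_shift()` integrates
$1/(\text{nm per pixel})$ from the reference wavelength. The reference is
the shortest calibrated wavelength, 445 nm: the calibration table fixes
only dispersion *differences*, and any constant offset is absorbed by
detector placement. Extrapolation outside the calibrated range is refused
rather than guessed.

`discretize_bands()` chooses the band grid so consecutive band centres are
separated by exactly `feature_px` (default 2) pixels of dispersion — the
step at which the smallest coded feature moves by its own width. Over
445–602 nm this yields $L = \lceil 68.57 / 2 \rceil = 35$ bands with
shifts $0, 2, \dots, 68$ px. Band edges are mapped back through the
inverse dispersion and clipped to the calibrated range, which makes the
two outermost bands slightly asymmetric; centres are kept strictly inside
their edges.

The published sensor-limited spatial extent does not follow uniquely from
the sensor name and the 2-pixel feature, so the spatial size of scenes is
fully configurable; nothing in the package assumes a particular grid.

## Reconstruction: augmented-Lagrangian ADMM

The inverse problem is solved with the augmented-Lagrangian form

$$\hat f = \arg\min_f \Psi(f) - \lambda_1^T (y - \Phi f)
  + \tfrac{\gamma_1}{2}\lVert y - \Phi f\rVert^2,$$

split by ADMM into a denoising subproblem in an auxiliary variable $v$, a
quadratic data-consistency subproblem in $f$, and multiplier updates:

* **Prior step** (`denoise_step()`):
  $v^i = \mathrm{prox}_{\Psi/\gamma_2}(f^{i-1} - \lambda_2/\gamma_2)$.
* **Projection step** (`projection_step()`): the exact minimizer
  $$f^i = (\gamma_2 I + \gamma_1 \Phi^T\Phi)^{-1}
    \left(\lambda_2 + \gamma_2 v^i + \Phi^T(\gamma_1 y - \lambda_1)\right).$$
  By the matrix-inversion lemma and the diagonal Gram this is computed in
  one shot: $A^{-1}b = \left(b - \Phi^T\!\big[(\Phi b) \oslash
  (\gamma_2/\gamma_1 + R)\big]\right)/\gamma_2$, elementwise division on
  the detector grid, no iterative linear solver and no dense matrix.
* **Multiplier step** (`update_multipliers()`):
  $\lambda_1 \leftarrow \lambda_1 - \gamma_1 (y - \Phi f^i)$,
  $\lambda_2 \leftarrow \lambda_2 - \gamma_2 (f^i - v^i)$.

`initialize_f0()` is the same solve applied to $\Phi^T y$.
`admm_reconstruct()` runs a fixed number of iterations in the order
denoise → project → multipliers. The printed recursions are ambiguous
about whether multiplier updates see $f^{i-1}$ or $f^i$ (they are mutually
inconsistent under either reading); the implementation updates multipliers
from the state's current `f`, `v` after the projection, which is the
standard scaled-ADMM ordering and makes the truth a fixed point of a full
iteration under a perfect prior — a property the tests assert.

### Design choices

* **Denoiser contract.** The deep-unfolding formulation uses a learned
  spectral-transformer denoiser and trains the penalties; at desk scale,
  without its weights, the package keeps the algorithmic skeleton and
  exposes the prior as a `denoiser()` spec: anisotropic total variation
  (default), identity, or any external callable. The guidance features a
  learned denoiser would condition on — the constant $\gamma_2$ map, the
  shifted-mask stack representing $\Phi$, and the per-pixel Gram diagonal
  (interpreting the "trace" feature as the diagonal map, since a scalar
  trace carries no spatial information) — are assembled by
  `guidance_features()` and passed through verbatim.
* **TV flavour.** Anisotropic, channel-independent spatial TV, with an
  optional band-axis term (`spectral_tv`, off by default). The proximal
  operator is solved by projected gradient on the dual with componentwise
  clipping and the safe step $1/(4 n_{\mathrm{dirs}} w)$; 20 inner sweeps
  by default. With weight $w = \mathrm{strength}/\gamma_2 = 0$ the prox is
  the identity, and constants are fixed points — both asserted in tests,
  and the prox has been checked against an independent quasi-Newton
  minimization of a smoothed objective.
* **Penalties.** $\gamma_1 = \gamma_2 = 1$ by default — the original
  method *learns* them, so no classical values exist — with an optional
  geometric schedule. Doubling $\gamma_1$ on noiseless data does not
  worsen the converged data residual (tested over 10 seeds).
* **Stopping.** A fixed iteration count only (the unfolded network fixes
  its depth); no tolerance-based early exit. Divergence raises an error
  naming the iteration.
* **Non-negativity.** Optional clamp after the *final* iteration only;
  clamping inside the loop would break the exactness of the projection
  algebra.

### What reconstruction quality to expect

Per-iteration diagnostics (data residual $\lVert y - \Phi f\rVert_2$,
splitting residual $\lVert f - v\rVert_2$) are returned as a tibble and
plotted by `autoplot()`. With noiseless data the iterates converge to the
TV-constrained data-consistent solution. How close that solution is to the
truth depends on how much of the scene's structure the measurements can
pin down: at the desk-scale study size used throughout the tests and the
acceptance script — 32×32 scenes, 8 bands, a 50% random mask with 2-pixel
features, shifts 0–14 px, i.e. 1472 detector pixels constraining 8192
voxels — spatially smooth scenes are recovered with high fidelity, while
scenes with dense fine structure (the default eye phantom's vessel
network) converge to about 20 dB PSNR: their gradient support is
comparable in size to the measurement budget, which is the regime where a
hand-crafted sparsity prior genuinely runs out of information. This is
precisely the gap the original system closes with a learned denoiser,
which is out of scope here; the acceptance script reports the PSNR the
classical TV prior actually attains rather than gating it. Field-averaged
*spectral* recovery is far easier than voxelwise recovery and comes back
well within a few percent at the same conditions.

## Resolution metrology

`usaf_frequency()` implements the USAF-1951 chart formula
$2^{g + (e-1)/6}$ lp/mm; `frequency_to_period()` converts to the full
line-pair period in micrometres. `michelson_contrast()` is
$(I_{\max}-I_{\min})/(I_{\max}+I_{\min})$, and `is_resolvable()` applies
the 0.4 decision threshold, counting a tie as resolvable (the rule's
source states no tie convention). `spectral_resolution()` is the
dispersion traversed by the smallest coded feature,
$\mathrm{feature\_px} \times \mathrm{nm/pixel}$, and
`average_spectral_resolution()` averages it weighted by each segment's
bandwidth (the unweighted mean rounds identically for the packaged
calibration).

Reported values are truncated to the printed precision (floor at one
decimal) rather than rounded half-up: truncation is the only rule
consistent with all six published figures (e.g. $2 \times 3.33 = 6.66
\rightarrow 6.6$ nm and $1000/64 = 15.625 \rightarrow 15.6$ µm). Exact
values are available via `digits = NULL`. In the combined report
(`resolution_report()`) the vertical-bar element labels the horizontal
resolution and vice versa; since that axis pairing is ambiguous in the
source, periods are labelled by element.

## Phantoms

Three generators emulate the validation experiments without any external
data; all are non-negative, seeded, and reproducible.

* `phantom_rainbow_letter()` — a letter silhouette behind a linear
  variable filter: each column carries a Gaussian passband whose centre
  sweeps linearly across the band range. The FWHM defaults to 12 nm, the
  middle of the 7–20 nm range quoted for the emulated filter, and the
  per-pixel spectrum is normalized to integrate to the configured
  intensity exactly.
* `phantom_usaf()` — three-bar USAF elements at exact chart geometry (bar
  length five times the width), rasterized by pixel-centre sampling, flat
  across bands (broadband illumination). Placement and the exact
  continuous bar widths are returned so `usaf_contrast_table()` can read
  contrast off any band or reconstruction.
* `phantom_eye()` — a smooth vignetted background with flat reflectance,
  overlaid by seeded random-walk vessels of decreasing width (one branch
  per vessel), carrying a smooth absorbing spectrum that dips mid-band.
  The spectra are synthetic smooth curves rather than literature
  hemoglobin tables — the physical phantom being emulated is painted, not
  perfused — which keeps the package download-free. The intensity-weighted
  field-averaged spectrum is recorded as ground truth.

What the phantoms do *not* emulate: chromatic PSF blur, lens aberrations,
illumination vignetting of the doughnut beam, relay magnification, or
sensor nonlinearity. Passing tests therefore demonstrate correctness of
the coding/dispersion/integration model and the optimizer, not robustness
to real optical non-idealities.

## Numerical choices and problem sizes

* Oracle tests densify $\Phi$ entry-by-entry from the scalar measurement
  definition on instances up to 12×12×4 and check forward, adjoint and
  projection to 1e-8, the adjoint identity to 1e-10, and exact
  diagonality of the densified Gram.
* Reconstruction tests and the acceptance script use 32×32×8 scenes
  (50 ADMM iterations) and a 64×64×8 end-to-end command-line run — sizes
  chosen so the whole suite completes in seconds while still exercising
  every code path at meaningful compression.
* On-disk cubes and measurements are 32-bit TIFF with a JSON sidecar
  holding wavelengths and the affine offset/scale of the stored samples
  (the TIFF writer stores unsigned integer samples in [0, 1]); round
  trips are exact to 32-bit quantization, about 2×10⁻¹⁰ of the value
  range. Masks are 8-bit PNG/TIFF binarized at threshold 128, so measured
  mask photographs can be dropped in directly.
* Degenerate inputs fail loudly: wavelengths outside the calibration,
  sub-feature wavelength ranges, sub-pixel USAF bars, all-zero contrast
  profiles, non-divisible mask dimensions, mismatched shapes.

## Limitations

* The learned denoiser and trained penalties of the original method are
  intentionally absent; reconstruction quality on structure-dense scenes
  is bounded by what hand-crafted TV can extract (see above).
* The dispersion model is a calibrated piecewise-linear table, not a
  physical glass model; only the packaged 445–602 nm calibration ships.
* Integer per-band shifts only; scenes requiring sub-pixel dispersion
  modelling are out of scope.
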