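---
title: "Global fitting of multi-channel single-molecule data: models, linking and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global fitting of multi-channel single-molecule data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(globfit)
```

This vignette documents the statistical model behind `globfit`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions that were genuinely open
when the package was written.

## The likelihood and parameter linking

A single fluorophore imaged in `n` channels produces pixel counts
`M_ki` that are independent Poisson draws around a model expectation
`mu_ki = N_i * PSF_i(x_i, y_i, z_i) + bg_i`. The fit minimizes the Poisson
deviance

$$\chi^2_{\mathrm{mle}} = 2\sum_i \sum_k \left[(\mu_{ki} - M_{ki}) -
  M_{ki}\,\ln(\mu_{ki}/M_{ki})\right],$$

with the logarithmic term restricted to pixels with `M_ki > 0`. The
deviance is twice the difference between the log-likelihood of the
saturated model and of the fitted model, so it is non-negative, zero at an
exact fit, and asymptotically chi-square for a correct model — which is
what the likelihood-based quality filter exploits.

Every fit parameter is declared **shared** or **local** in a `link_spec`.
A shared parameter `theta` enters channel `i` as
`theta_i = S_i * theta + dtheta_i`. The scale `S_i` expresses fixed
relations between channels: a 1:1 biplane photon split is `S = (0.5, 0.5)`
on a shared total `N`; a dye with dark/bright photon ratio `r` is
`S = (1/(1+r), r/(1+r))`; a mirrored channel carries `S_x = -1`. The
translation `dtheta_i` for x and y is the per-ROI residual shift `s`
between the channel's transformed candidate position and the integer pixel
at which its ROI was actually cut, so the geometric channel registration
enters the fit exactly once and the fitted position lives in reference
coordinates.

The score `J` is defined as `-(1/2) d(chi2)/d(theta)` — the derivative of
the log-likelihood — and the curvature `H` is the Fisher-style
Gauss–Newton form `sum dmu_m dmu_n M / mu^2`, both accumulated with the
`S`-scaling of the linking. Shared rows sum contributions over channels;
local parameters of different channels never mix. Within one channel the
cross terms between two different *local* parameters are dropped from `H`
(their diagonal is kept); this diagonal-local approximation is the default
and can be disabled (`fit_controls(full_hessian = TRUE)`). We compared the
two on simulated biplane and 4Pi data and found identical optima, with the
full form occasionally saving one or two iterations; since either `H` is
only a preconditioner for the damped update, the approximation affects the
path, not the optimum. The Cramér–Rao computation (`compute_crlb`) always
uses the exact Fisher matrix (cross-channel local terms are exactly zero;
within-channel terms are kept), because the bound is a property of the
model, not of the optimizer.

## Levenberg–Marquardt controls

The update solves `(H + lambda * diag(H)) dtheta = J`. Defaults (all in
`fit_controls()`): `lambda` starts at 0.1, divides by 10 on an accepted
step (floor 1e-7), multiplies by 10 on a rejected one (cap 1e7, after
which the fit is flagged non-converged); convergence is declared after two
consecutive accepted steps with a relative deviance decrease below 1e-6;
at most 100 accepted iterations. Parameters are projected onto bounds
after every accepted step: x and y within the ROI ± 1 px, z within the
calibrated range, `N >= 1e-3`, `bg >= 0`. The expected value `mu` is
floored at 1e-6 photons/pixel so the log-likelihood stays finite at
model zeros.

Initialization: background from the median ROI border pixel; photons from
the background-subtracted pixel sum; position from photon-weighted
centroids mapped back through the residual shifts. The axial start comes
from matching windowed second moments of the background-subtracted ROI
against width curves `sigma_x(z)`, `sigma_y(z)` tabulated from the model
itself (an 11×11 window around the centroid suppresses the positive halo
that clipping Poisson background at zero otherwise adds to whole-ROI
moments — without the window the start is biased towards the ends of the
z range). Width-encoded axial information is often two-fold ambiguous
(defocus branches), so both the best and the best well-separated local
minimum of the moment cost are used as starts and the deviance decides.
For interferometric fits the fringe phase is initialized from the
quadrature of the four channel photon sums, re-synchronized to every
axial start (`phi = psi - 2 k_z z_start`), and the start set additionally
contains the two half-fringe-period neighbours; without these two
measures a percent-level fraction of fits converges to a neighbouring
fringe and inflates the axial error tenfold. When several axial starts
exist, each is explored with a short iteration budget (15 accepted steps)
and only the best basin is iterated to convergence — the basins differ by
large deviance gaps well before convergence, so the pruning changes the
path, not the selected optimum.

## PSF models

**Tricubic spline** (`fit_cspline`): per-voxel coefficients from function
values and central-difference derivatives at the voxel corners (separable
Catmull–Rom construction). The spline interpolates the calibrated stack
at its samples and is C1 across voxel boundaries; boundary voxels use
replicated neighbours, lateral evaluation outside the support clamps to
the edge, axial evaluation outside the range is an error. Small negative
undershoots of the interpolant are clamped to zero with their derivatives,
consistently with the likelihood floor.

**Astigmatic Gaussian** (`gaussian_psf`): pixel-integrated Gaussian with
`sigma(z) = sigma0 * sqrt(1 + u^2 + A u^3 + B u^4)`, `u = (z - gamma)/d`,
per axis; `gamma` carries both the channel's focal-plane offset and the
astigmatic x/y split.

**Simplified interferometric model** (`fourpi_psf`): an incoherent
envelope multiplied by `1 + m cos(2 k_z z + phi + offset_i)` with
quadrature offsets (0, π/2, π, 3π/2). This is a deliberate simplification:
experimental interferometric PSFs modulate *shape*, not just amplitude,
within each phase image. One consequence is that with per-channel photon
parameters the set `(phi, N_1..N_4)` is exactly one-dimensionally
degenerate (any phase change can be absorbed into the four amplitudes), so
in that linking scheme the phase carries no information and axial
precision is envelope-limited; with photons linked the same holds because
the phase remains free. The 4Pi benchmarks therefore compare
envelope-level axial precision between linking schemes, which is the
quantity this model can support honestly. `fourpi_z_from_phase` documents
the phase-to-z post-processing used when the cavity phase is known.

**Scalar-diffraction stand-in** (`pupil_psf_stack`,
`make_biplane_spline_psfs`): biplane benchmarks need a PSF whose shape
changes with z the way experimental bead calibrations do. The default
biplane pair is computed from a pupil function (NA 1.43, n 1.518, 668 nm,
100 nm pixels) with 100 mλ of spherical aberration, planes ±200 nm,
sampled every 25 nm over ±800 nm and converted to splines. The aberration
level is the typical residual of high-NA oil objectives and matches the
magnitude quoted for aberrations in comparable simulation work; it breaks
the axial symmetry of the defocus curves so that single-channel fitting is
possible (weakly), while the plane pairing provides the strong axial
encoding. A width-parameterized Gaussian pair cannot reproduce this
structure: we verified from Fisher matrices that for any Gaussian-width
biplane the per-channel-fit-plus-averaging penalty in z is only 2–12%,
whereas experimental spline PSFs show substantially larger penalties.

## The synthetic-data generator

`simulate_rois`, `simulate_multicolor`, `simulate_fourpi` and
`simulate_bead_stacks` render expected images through the same
`evaluate_channel` code the fitter uses and add only Poisson noise — no
camera excess noise, no read noise, no drift, no multi-emitter overlap.
Default conditions: biplane 5000 photons split 1:1 with 40 total
background photons per pixel (20 per channel), 15×15 px ROIs, z on a grid
over ±600 nm; multicolor dyes at photon ratios 0.39/0.21/0.07/0.02 with a
log-normal total-photon distribution (mean 3000, CV 0.5 — a stand-in for
experimental photon distributions, which are not tabulated anywhere we
could use); 4Pi with 2000 photons and 20 background photons per pixel per
objective, distributed over the four phase channels (mean 1000 photons,
10 bg per channel), lateral positions uniform within ±1 px of the ROI
center, and the fringe phase following the axial position (a zero cavity
offset; a `phi_mode = "random"` switch draws the cavity phase instead).
Bead stacks place beads at known positions, map target channels through a
known transform, and are the fixture for the calibration round trip.

Passing tests on these simulations shows that the estimator is efficient
and unbiased *under the generating model*; it does not demonstrate
robustness to camera noise models, overlapping emitters, or PSF model
mismatch on real data.

## Calibration and pipeline choices

Bead calibration follows candidate detection on the Gaussian-filtered
z-mean image (threshold 0.2 of the robust maximum by default, so synthetic
tests are scale-free), transform-aware ROI cutting with cubic sub-pixel
resampling of target channels, two rounds of 3D cross-correlation
registration against an iteratively refined template (the second round
registers the central half of the z range), rejection of beads whose
normalized template correlation falls below 0.9, normalization by the sum
of the central reference slice, and a per-pixel cubic smoothing spline
along z (degrees of freedom 0.6 × number of slices; on noiseless input
this deviates well under 1% RMS from the raw axial profiles) before the
spline fit. When no transform is supplied it is bootstrapped from
per-channel bead positions (≥ 4 beads: centroid anchors plus the
link/fit loop; fewer: translation-only from image cross-correlation).
The calibration is validated by refitting every bead at every slice and
comparing fitted z with the slice's nominal z.

Candidate detection on movies uses a difference of Gaussians
(sigma 1.0/2.5 px) with a threshold of 4 robust noise units by default;
candidates from all channels are mapped to the reference channel and
merged by single linkage within 2 px (union semantics, so molecules dim
in one channel survive). Plateau ties in maximum finding break to the
smallest (row, col) index for reproducibility. The likelihood filter
simulates the deviance distribution under the fitted model (per photon
bin) rather than assuming a chi-square, because the deviance of low-count
Poisson pixels is visibly non-chi-square.

## Benchmark scales

The packaged benchmarks use 200 molecules per z step (25 steps of 50 nm
for biplane, 17 steps for 4Pi), 500 molecules for the paired color
comparison and 5 beads for the calibration round trip. These sizes put
the sampling error of an RMSE estimate near 5% (1/sqrt(2n)), small enough
to compare against the Cramér–Rao bound at the stated 20% margin while
keeping a full run in the ten-minute range on one core.

## Known limitations

- The interferometric model is amplitude-modulated only; phase-carried
  axial information under per-channel photon linking is therefore absent
  by construction (see above).
- No sCMOS per-pixel noise model; the likelihood is pure Poisson.
- Single-emitter fitting only; overlapping molecules bias the fit and are
  meant to be removed by the deviance filter.
- Transforms are 2D (projective/affine/polynomial); no z-dependent
  chromatic mapping.
- The calibration's transform bootstrap uses centroid anchors, which is
  less precise than fitting each bead with a single-channel spline model;
  with ≥ 4 well-separated bright beads the residual field error is a few
  hundredths of a pixel, which the linked-fit residual shifts absorb.
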