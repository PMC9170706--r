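# globfit

Global maximum-likelihood fitting for multi-channel single-molecule
localization microscopy (SMLM), in R.

Many SMLM modalities split the emission of one fluorophore over two or more
camera channels: biplane detection (two axially offset focal planes),
ratiometric multicolor imaging (two spectral channels), and interferometric
4Pi-SMLM (four phase channels). The channels are usually fitted one by one
and their parameters combined afterwards, which discards the fact that the
underlying molecule is the same in every channel. `globfit` instead
maximizes the joint Poisson likelihood over all channels while *linking*
selected parameters across them, which improves localization precision and
makes color assignment more reliable.

## The model

For measured photon counts `M_ki` (pixel `k`, channel `i`) and a PSF model
producing expected counts `mu_ki(theta)`, the fitter minimizes the Poisson
deviance

    chi2_mle = 2 * sum_ik [ (mu_ki - M_ki) - M_ki * log(mu_ki / M_ki) ],

(the log term restricted to `M_ki > 0`). Each fit parameter — x, y, z,
photons N, background bg, and the interference phase phi for 4Pi — is
either *local* (one value per channel) or *shared*; a shared parameter
maps into channel `i` as

    theta_i = S_i * theta + dtheta_i,

where `S_i` is a per-channel scale (e.g. a fixed photon split) and
`dtheta_i` a translation; for x and y the translation is the sub-pixel
residual `s` between the transformed and the rounded ROI origin of that
channel. Minimization uses a damped Levenberg–Marquardt iteration solving
`(H + lambda * diag(H)) dtheta = J`, where `J` is the score
(`-1/2 d(chi2)/d(theta)`) and `H` a Fisher-style curvature accumulated with
the same shared/local layout. Per-parameter uncertainties come from the
Cramér–Rao lower bound (inverse Fisher information) of the linked model.

PSF models: piecewise tricubic splines calibrated from bead z-stacks,
pixel-integrated astigmatic Gaussians with the standard polynomial width
curve, and a simplified interferometric model (envelope times cosine
fringe) for 4Pi. A scalar-diffraction (pupil function) generator renders
realistic aberrated PSF stacks for simulations.

The surrounding pipeline covers channel-transform estimation from point
sets, multi-channel spline-PSF calibration from bead stacks, candidate
detection (difference of Gaussians) and cross-channel ROI extraction,
merging and quality filtering of localizations, and ratiometric /
fixed-photon-ratio color assignment.

## Worked example

Simulate a small biplane data set, fit it globally with all parameters
shared, and compare the axial scatter with the theoretical bound:

```r
library(globfit)

psfs <- make_biplane_spline_psfs()          # two planes, 400 nm apart
cfg  <- sim_config("biplane", photons = 5000, bg_total = 40,
                   z_grid = c(-300, 0, 300), n_per_z = 50, seed = 1)
sim  <- simulate_rois(psfs, cfg)

link <- link_spec(2, shared = c("x", "y", "z", "N", "bg"),
                  S = list(N = c(0.5, 0.5)))
fit  <- fit_rois_global(sim$rois, psfs, link)

for (zv in unique(sim$truth$z)) {
  sel <- sim$truth$z == zv
  cat(sprintf("z = %4.0f nm: RMSE_z = %4.1f nm, sqrt(CRLB_z) = %4.1f nm\n",
              zv, sqrt(mean((fit$z[sel] - zv)^2)),
              sqrt(mean(fit$crlb_z[sel]))))
}
#> z = -300 nm: RMSE_z = 12.4 nm, sqrt(CRLB_z) = 15.3 nm
#> z =    0 nm: RMSE_z =  8.0 nm, sqrt(CRLB_z) =  8.0 nm
#> z =  300 nm: RMSE_z =  5.4 nm, sqrt(CRLB_z) =  7.4 nm
```

Each row compares the measured root-mean-square z error of 50 fits at that
true z with the mean Cramér–Rao bound reported per fit: the global fit is
essentially efficient (RMSE tracks the bound) across the axial range. The
returned table also carries `x`, `y`, per-channel photons, `chi2`,
iteration counts and convergence flags.

Fixed-ratio color assignment works the same way through
`fit_fixed_ratio()`, which refits every molecule once per dye hypothesis
with the photon split clamped to that dye's calibrated ratio and keeps the
maximum-likelihood dye.

A thin command-line wrapper is installed at `inst/cli/globfit.R`
(`simulate`, `transform`, `calibrate`, `localize`, `colors`, `run`
subcommands).

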