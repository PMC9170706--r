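# Synthetic-data generator: renders Poisson-noise multi-channel single
# molecule ROIs and bead calibration z-stacks from known PSF models, with
# the ground truth stored next to every ROI. Default conditions follow the
# standard simulation protocols for biplane (5000 photons split 1:1, 40
# total background photons), four-color ratiometric (dye ratios
# 0.39/0.21/0.07/0.02) and interferometric 4Pi (2000 photons per objective,
# 20 background photons per pixel per objective) imaging.

#' Default biplane PSF pair
#'
#' Two Gaussian channels whose focal planes are separated axially (default
#' ~400 nm), the stand-in for an experimental biplane calibration. Biplane
#' detection encodes z purely through defocus, so the default pair is not
#' astigmatic; a non-zero cubic term `A` gives the defocus curves the
#' axial asymmetry that experimental PSFs show (and that makes z
#' identifiable, up to noise, in a single channel).
#'
#' @param plane_distance axial separation of the two focal planes (nm).
#' @param sigma0 focal width (pixels).
#' @param d depth of focus (nm).
#' @param astig_gamma astigmatic focal offset per axis (nm); 0 (default)
#'   gives a purely defocus-encoded pair.
#' @param A cubic asymmetry of the defocus curve.
#' @param z_range valid range (nm).
#' @return list of two [gaussian_psf()] models.
#' @export
make_biplane_psfs <- function(plane_distance = 400, sigma0 = 1.1, d = 350,
                              astig_gamma = 0, A = 0.35,
                              z_range = c(-800, 800)) {
  lapply(c(-1, 1) * plane_distance / 2, function(f)
    gaussian_psf(sigma0 = c(sigma0, sigma0),
                 gamma = c(f + astig_gamma, f - astig_gamma),
                 d = d, A = c(A, A), z_range = z_range))
}

#' Default dual-channel astigmatic PSF for ratiometric imaging
#' @inheritParams make_biplane_psfs
#' @return list of two identical [gaussian_psf()] models.
#' @export
make_astig_psfs <- function(sigma0 = 1.1, d = 350, astig_gamma = 180,
                            z_range = c(-800, 800)) {
  p <- gaussian_psf(sigma0 = c(sigma0, sigma0),
                    gamma = c(astig_gamma, -astig_gamma), d = d,
                    z_range = z_range)
  list(p, p)
}

#' Default simplified 4Pi PSF
#'
#' Mildly astigmatic Gaussian envelope with a cosine interference fringe in
#' four quadrature phase channels.
#'
#' @param m modulation depth.
#' @param k_z axial wavenumber (rad/nm).
#' @param astig_gamma envelope astigmatism (nm).
#' @inheritParams make_biplane_psfs
#' @return a [fourpi_psf()].
#' @export
make_fourpi_psf <- function(m = 0.9, k_z = 2 * pi * 1.35 / 668,
                            sigma0 = 1.1, d = 350, astig_gamma = 100,
                            z_range = c(-600, 600)) {
  fourpi_psf(gaussian_psf(sigma0 = c(sigma0, sigma0),
                          gamma = c(astig_gamma, -astig_gamma), d = d,
                          z_range = z_range),
             m = m, k_z = k_z)
}

#' Simulation configuration
#'
#' @param modality `"biplane"`, `"astig2color"` or `"fourpi"`.
#' @param photons total detected photons per molecule (biplane/multicolor)
#'   or photons per objective (4Pi).
#' @param split per-channel photon fractions (must sum to 1); default 1:1.
#' @param bg_total total background photons per pixel summed over channels
#'   (split equally).
#' @param z values: either `z_grid` (vector, `n_per_z` molecules at each) or
#'   `z_range` with `n` molecules placed uniformly.
#' @param n_per_z molecules per z grid point.
#' @param n molecules for uniform-z mode.
#' @param roi_size ROI side length (pixels).
#' @param xy `"center"` (molecule at the ROI center) or `"uniform1"`
#'   (uniform within +/-1 pixel of the center).
#' @param seed RNG seed fixing the full output stream.
#' @export
sim_config <- function(modality = c("biplane", "astig2color", "fourpi"),
                       photons = 5000, split = NULL, bg_total = 40,
                       z_grid = NULL, n_per_z = 100, z_range = c(-600, 600),
                       n = 1000, roi_size = 15,
                       xy = c("center", "uniform1"), seed = 1L) {
  modality <- match.arg(modality)
  xy <- match.arg(xy)
  stopifnot(photons > 0, bg_total >= 0)
  list(modality = modality, photons = photons, split = split,
       bg_total = bg_total, z_grid = z_grid, n_per_z = n_per_z,
       z_range = z_range, n = n, roi_size = roi_size, xy = xy,
       seed = as.integer(seed))
}

# draw true molecule parameters from a config
sim_truth <- function(config, n_channels) {
  if (!is.null(config$z_grid)) {
    z <- rep(config$z_grid, each = config$n_per_z)
  } else {
    z <- stats::runif(config$n, config$z_range[1], config$z_range[2])
  }
  nmol <- length(z)
  ctr <- (config$roi_size - 1) / 2
  if (config$xy == "uniform1") {
    x <- ctr + stats::runif(nmol, -1, 1)
    y <- ctr + stats::runif(nmol, -1, 1)
  } else {
    x <- rep(ctr, nmol); y <- rep(ctr, nmol)
  }
  split <- config$split
  if (is.null(split)) split <- rep(1 / n_channels, n_channels)
  stopifnot(abs(sum(split) - 1) < 1e-9)
  data.frame(mol = seq_len(nmol), x = x, y = y, z = z,
             N_total = config$photons,
             bg = config$bg_total / n_channels)
}

#' Simulate multi-channel single-molecule ROIs
#'
#' Renders the expected image of every channel from the PSF set and the
#' configured photon split, then adds independent Poisson noise per pixel.
#'
#' @param psfs per-channel PSF models (list, or a single `fourpi_psf`).
#' @param config a [sim_config()].
#' @return list with `rois` (list of [multichannel_roi()]) and `truth`
#'   (data.frame, one row per molecule).
#' @export
simulate_rois <- function(psfs, config) {
  set.seed(config$seed)
  if (inherits(psfs, "fourpi_psf")) return(simulate_fourpi(psfs, config))
  nch <- if (inherits(psfs, "psf_model")) 2L else length(psfs)
  psfs <- as_psf_set(psfs, nch)
  split <- config$split
  if (is.null(split)) split <- rep(1 / nch, nch)
  truth <- sim_truth(config, nch)
  for (i in seq_len(nch)) truth[[paste0("N_ch", i)]] <- truth$N_total * split[i]
  rois <- lapply(seq_len(nrow(truth)), function(r) {
    M <- lapply(seq_len(nch), function(i) {
      mu <- evaluate_channel(psfs[[i]],
                             list(x = truth$x[r], y = truth$y[r],
                                  z = truth$z[r],
                                  N = truth$N_total[r] * split[i],
                                  bg = truth$bg[r]),
                             config$roi_size, channel = i)
      matrix(stats::rpois(length(mu), mu), config$roi_size, config$roi_size)
    })
    multichannel_roi(M, frame = r)
  })
  list(rois = rois, truth = truth)
}

#' Simulate four-channel interferometric (4Pi) ROIs
#'
#' `config$photons` is interpreted per objective: with two objectives and
#' four phase channels the mean expected photons per channel is
#' `photons / 2`, and the per-channel background is `bg_total / 2 / 4`
#' when `bg_total` is given per objective... see Details.
#'
#' @details The per-channel envelope photon parameter is
#' `N = 2 * photons / 4` and the per-channel background is
#' `2 * bg_total / 4`, i.e. the light of both objectives distributed over
#' the four phase images. The interference phase follows the axial position
#' (`phi_true = 0` cavity offset), so the fringe argument is `2 k_z z`.
#'
#' @param psf a [fourpi_psf()].
#' @param config a [sim_config()] (modality `"fourpi"`).
#' @param phi_mode `"coupled"` (cavity phase 0 for all molecules) or
#'   `"random"` (uniform cavity phase per molecule).
#' @export
simulate_fourpi <- function(psf, config, phi_mode = c("coupled", "random")) {
  phi_mode <- match.arg(phi_mode)
  stopifnot(inherits(psf, "fourpi_psf"))
  set.seed(config$seed)
  nch <- psf_n_channels(psf)
  truth <- sim_truth(config, nch)
  truth$N_channel <- 2 * config$photons / nch
  truth$bg <- 2 * config$bg_total / nch
  truth$phi <- if (phi_mode == "random")
    stats::runif(nrow(truth), -pi, pi) else 0
  rois <- lapply(seq_len(nrow(truth)), function(r) {
    M <- lapply(seq_len(nch), function(i) {
      mu <- evaluate_channel(psf,
                             list(x = truth$x[r], y = truth$y[r],
                                  z = truth$z[r], N = truth$N_channel[r],
                                  bg = truth$bg[r], phi = truth$phi[r]),
                             config$roi_size, channel = i)
      matrix(stats::rpois(length(mu), mu), config$roi_size, config$roi_size)
    })
    multichannel_roi(M, frame = r)
  })
  list(rois = rois, truth = truth)
}

#' Simulate a ratiometric multicolor data set
#'
#' Draws a dye per molecule, a total photon count from a log-normal
#' distribution, splits the photons between the spectral channels by the
#' dye's ratio and renders Poisson-noise dual-channel ROIs.
#'
#' @param psfs dual-channel PSF set.
#' @param ratios a [dye_ratio_set()] or numeric I2/I1 ratios.
#' @param n number of molecules.
#' @param photon_mean mean total photons per molecule.
#' @param photon_cv coefficient of variation of the log-normal photon
#'   distribution (0 for fixed photons).
#' @param bg_total total background photons/pixel (split equally).
#' @param z_range axial range (nm), uniform placement.
#' @param roi_size ROI side length.
#' @param priors per-dye selection probabilities (default uniform).
#' @param seed RNG seed.
#' @export
simulate_multicolor <- function(psfs, ratios, n = 1000, photon_mean = 3000,
                                photon_cv = 0.5, bg_total = 40,
                                z_range = c(-600, 600), roi_size = 15,
                                priors = NULL, seed = 1L) {
  if (!is.data.frame(ratios)) ratios <- dye_ratio_set(ratios)
  psfs <- as_psf_set(psfs, 2L)
  set.seed(as.integer(seed))
  k <- nrow(ratios)
  if (is.null(priors)) priors <- rep(1 / k, k)
  dye <- sample.int(k, n, replace = TRUE, prob = priors)
  if (photon_cv > 0) {
    sdlog <- sqrt(log(1 + photon_cv^2))
    Ntot <- stats::rlnorm(n, log(photon_mean) - sdlog^2 / 2, sdlog)
  } else {
    Ntot <- rep(photon_mean, n)
  }
  z <- stats::runif(n, z_range[1], z_range[2])
  ctr <- (roi_size - 1) / 2
  truth <- data.frame(mol = seq_len(n), dye = ratios$label[dye],
                      dye_index = dye, x = ctr, y = ctr, z = z,
                      N_total = Ntot,
                      N_ch1 = Ntot * ratios$S1[dye],
                      N_ch2 = Ntot * ratios$S2[dye],
                      bg = bg_total / 2)
  rois <- lapply(seq_len(n), function(r) {
    M <- lapply(1:2, function(i) {
      mu <- evaluate_channel(psfs[[i]],
                             list(x = truth$x[r], y = truth$y[r],
                                  z = truth$z[r],
                                  N = truth[[paste0("N_ch", i)]][r],
                                  bg = truth$bg[r]), roi_size, channel = i)
      matrix(stats::rpois(length(mu), mu), roi_size, roi_size)
    })
    multichannel_roi(M, frame = r)
  })
  list(rois = rois, truth = truth, ratios = ratios)
}

#' Render noiseless expected ROIs (no Poisson draw)
#'
#' Companion to [simulate_multicolor()] for noiseless-limit checks.
#' @param psfs dual-channel PSF set.
#' @param truth a truth data.frame as produced by the simulators.
#' @param roi_size ROI side length.
#' @export
expected_rois <- function(psfs, truth, roi_size = 15) {
  nch <- length(grep("^N_ch", names(truth)))
  psfs <- as_psf_set(psfs, nch)
  lapply(seq_len(nrow(truth)), function(r) {
    M <- lapply(seq_len(nch), function(i)
      evaluate_channel(psfs[[i]],
                       list(x = truth$x[r], y = truth$y[r], z = truth$z[r],
                            N = truth[[paste0("N_ch", i)]][r],
                            bg = truth$bg[r]), roi_size, channel = i))
    multichannel_roi(M, frame = r)
  })
}

#' Simulate bead calibration z-stacks for several channels
#'
#' Renders bright beads at fixed lateral positions through every z slice;
#' the target channel sees the beads at positions mapped by the true
#' transform. Ground truth (positions, transform) is returned for
#' round-trip calibration tests.
#'
#' @param psfs per-channel PSF models.
#' @param transform true [channel_transform()] mapping reference to target
#'   coordinates (list for > 2 channels; identity for channel 1).
#' @param bead_xy matrix of bead positions (x, y) in reference pixels.
#' @param z_positions slice z values (nm).
#' @param photons bead photons per slice and channel.
#' @param bg background photons/pixel.
#' @param size image side length (pixels).
#' @param noise add Poisson noise (TRUE) or keep expectations.
#' @param seed RNG seed.
#' @return list with `stacks` (per-channel 3D arrays `[y, x, z]`),
#'   `z_positions`, `bead_xy`, `transform`.
#' @export
simulate_bead_stacks <- function(psfs, transform, bead_xy,
                                 z_positions = seq(-600, 600, by = 20),
                                 photons = 2e4, bg = 2, size = 64,
                                 noise = TRUE, seed = 1L) {
  set.seed(as.integer(seed))
  nch <- length(psfs)
  bead_xy <- matrix(bead_xy, ncol = 2)
  if (nrow(bead_xy) > 1) {
    dmin <- min(stats::dist(bead_xy))
    if (dmin < 10) warning("beads closer than 10 px may overlap")
  }
  tfs <- if (inherits(transform, "channel_transform")) {
    c(list(identity_transform()), rep(list(transform), nch - 1))
  } else c(list(identity_transform()), transform)
  stacks <- lapply(seq_len(nch), function(i) {
    pos <- apply_transform(tfs[[i]], bead_xy)
    arr <- array(0, c(size, size, length(z_positions)))
    for (k in seq_along(z_positions)) {
      img <- matrix(bg, size, size)
      for (b in seq_len(nrow(pos))) {
        img <- img + photons *
          matrix(psf_eval_raw(psfs[[i]], pos[b, 1], pos[b, 2],
                              z_positions[k], size)$val, size, size)
      }
      arr[, , k] <- if (noise) matrix(stats::rpois(size * size, img), size)
                    else img
    }
    arr
  })
  list(stacks = stacks, z_positions = z_positions, bead_xy = bead_xy,
       transform = tfs)
}
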