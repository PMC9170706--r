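# Simplified interferometric (4Pi) PSF: an incoherent envelope modulated by a
# cosine fringe. The expected image in phase channel i is
#   mu = N * I(x, y, z) * (1 + m * cos(2 k_z z + phi + offset_i)) + bg,
# where I is the envelope PSF (spline or astigmatic Gaussian), m the
# modulation depth, k_z the axial wavenumber and phi a free interference
# phase offset (cavity phase). This cosine model is a deliberate
# simplification of experimental interferometric PSF constructions; it keeps
# the quadrature structure of the four phase channels while staying fully
# analytic.

#' Simplified four-channel interferometric PSF
#'
#' @param envelope an envelope PSF model ([gaussian_psf()] or a
#'   `cspline_psf`), normalized to unit lateral sum.
#' @param m modulation depth in \[0, 1\].
#' @param k_z axial wavenumber in rad/nm; the fringe period along z is
#'   `pi / k_z`. Default corresponds to silicone-immersion detection at
#'   668 nm emission (n = 1.35).
#' @param offsets per-channel phase offsets in radians.
#' @return object of class `c("fourpi_psf", "psf_model")`.
#' @export
fourpi_psf <- function(envelope, m = 0.9, k_z = 2 * pi * 1.35 / 668,
                       offsets = c(0, pi / 2, pi, 3 * pi / 2)) {
  if (m < 0 || m > 1) stop("modulation depth m must lie in [0, 1]")
  stopifnot(inherits(envelope, "psf_model"), k_z > 0)
  obj <- list(envelope = envelope, m = m, k_z = k_z, offsets = offsets)
  class(obj) <- c("fourpi_psf", "psf_model")
  obj
}

#' @export
psf_param_names.fourpi_psf <- function(psf) c("x", "y", "z", "N", "bg", "phi")

#' @export
psf_z_range.fourpi_psf <- function(psf) psf_z_range(psf$envelope)

#' Number of channels a PSF model describes (1 unless interferometric)
#' @param psf a PSF model.
#' @export
psf_n_channels <- function(psf) UseMethod("psf_n_channels")
#' @export
psf_n_channels.psf_model <- function(psf) 1L
#' @export
psf_n_channels.fourpi_psf <- function(psf) length(psf$offsets)

psf_eval_raw.fourpi_psf <- function(psf, x, y, z, roi_size, chan = 1L,
                                    phi = 0, ...) {
  if (chan > length(psf$offsets)) stop("channel index exceeds phase offsets")
  env <- psf_eval_raw(psf$envelope, x, y, z, roi_size)
  arg <- 2 * psf$k_z * z + phi + psf$offsets[chan]
  fac <- 1 + psf$m * cos(arg)
  dfac <- -psf$m * sin(arg)
  D <- matrix(0, length(env$val), 4L,
              dimnames = list(NULL, c("x", "y", "z", "phi")))
  D[, 1L] <- env$dval[, 1L] * fac
  D[, 2L] <- env$dval[, 2L] * fac
  D[, 3L] <- env$dval[, 3L] * fac + env$val * dfac * 2 * psf$k_z
  D[, 4L] <- env$val * dfac
  list(val = env$val * fac, dval = D)
}

#' Expected photon image of one channel
#'
#' Composes the normalized PSF with photons and background:
#' `mu = N * psf(x, y, z) + bg`, floored at a small positive value so the
#' Poisson likelihood stays finite.
#'
#' @param psf a PSF model.
#' @param params named list or vector with `x`, `y` (ROI pixels), `z` (nm),
#'   `N` (photons), `bg` (photons/pixel) and, for interferometric models,
#'   `phi` (rad).
#' @param roi_size ROI side length in pixels (odd).
#' @param channel channel index (interferometric models only).
#' @param mu_floor lower clamp on the expected value (photons/pixel).
#' @return `roi_size x roi_size` matrix of expected photons.
#' @export
evaluate_channel <- function(psf, params, roi_size, channel = 1L,
                             mu_floor = 1e-6) {
  p <- as.list(params)
  if (p$N < 0 || p$bg < 0) stop("N and bg must be non-negative")
  raw <- if (inherits(psf, "fourpi_psf")) {
    psf_eval_raw(psf, p$x, p$y, p$z, roi_size, chan = channel,
                 phi = if (is.null(p$phi)) 0 else p$phi)
  } else {
    psf_eval_raw(psf, p$x, p$y, p$z, roi_size)
  }
  mu <- pmax(p$N * raw$val + p$bg, mu_floor)
  matrix(mu, roi_size, roi_size)
}

#' Expected image and its first derivatives
#'
#' @inheritParams evaluate_channel
#' @return list with `mu` (vector, column-major over the ROI) and `D`, a
#'   matrix of per-pixel partial derivatives with one named column per fit
#'   parameter (`x`, `y`, `z`, `N`, `bg` and `phi` where applicable).
#' @export
evaluate_derivatives <- function(psf, params, roi_size, channel = 1L,
                                 mu_floor = 1e-6) {
  p <- as.list(params)
  raw <- if (inherits(psf, "fourpi_psf")) {
    psf_eval_raw(psf, p$x, p$y, p$z, roi_size, chan = channel,
                 phi = if (is.null(p$phi)) 0 else p$phi)
  } else {
    psf_eval_raw(psf, p$x, p$y, p$z, roi_size)
  }
  mu <- pmax(p$N * raw$val + p$bg, mu_floor)
  npx <- length(raw$val)
  k <- ncol(raw$dval)
  has_phi <- k == 4L
  cn <- if (has_phi) c("x", "y", "z", "N", "bg", "phi") else
    c("x", "y", "z", "N", "bg")
  D <- matrix(0, npx, length(cn), dimnames = list(NULL, cn))
  D[, 1:3] <- raw$dval[, 1:3] * p$N
  D[, 4L] <- raw$val
  D[, 5L] <- 1
  if (has_phi) D[, 6L] <- raw$dval[, 4L] * p$N
  list(mu = mu, D = D)
}

#' Expected image of one interferometric phase channel
#'
#' Convenience wrapper around [evaluate_channel()] for `fourpi_psf` models.
#'
#' @param psf a [fourpi_psf()].
#' @param params as in [evaluate_channel()], including `phi`.
#' @param channel_index phase-channel index.
#' @param roi_size ROI side length.
#' @export
evaluate_fourpi <- function(psf, params, channel_index, roi_size) {
  stopifnot(inherits(psf, "fourpi_psf"))
  evaluate_channel(psf, params, roi_size, channel = channel_index)
}

#' Convert a fitted interference phase into a refined z position
#'
#' The fringe phase measures z modulo the fringe period `pi / k_z`; the
#' envelope z estimate selects the period. Returns the z whose phase matches
#' `phi` (plus the cavity offset `phi0`) closest to `z_env`.
#'
#' @param z_env envelope z estimates (nm).
#' @param phi fitted phase offsets (rad).
#' @param k_z axial wavenumber (rad/nm).
#' @param phi0 cavity phase at z = 0 used in the simulation/experiment.
#' @export
fourpi_z_from_phase <- function(z_env, phi, k_z, phi0 = 0) {
  # the fit pins down the total fringe phase 2 k_z z + phi; replacing the
  # fitted cavity offset by its true value phi0 and keeping the total phase
  # fixed moves z by wrap(phi - phi0) / (2 k_z), the wrap choosing the
  # fringe period closest to the envelope estimate
  z_env + wrap_phase(phi - phi0) / (2 * k_z)
}
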