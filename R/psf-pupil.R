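# Scalar-diffraction PSF generator: computes realistic aberrated PSF
# z-stacks from a pupil function (circular aperture, defocus phase, Zernike
# spherical aberration) by FFT, integrates them onto camera pixels and
# wraps them into the spline representation. Serves as the synthetic
# stand-in for an experimental bead-calibrated PSF: unlike a Gaussian width
# model, its shape changes with z in a non-separable way, so per-channel
# photon/background estimates couple to z the way experimental PSFs do.

#' Render an aberrated scalar-diffraction PSF z-stack
#'
#' @param z_positions slice z values (nm).
#' @param defocus_offset focal-plane offset of this channel (nm); positive
#'   moves the focus to positive z.
#' @param sph_mlambda spherical aberration (Zernike Z(4,0)) amplitude in
#'   milli-lambda rms.
#' @param ast_mlambda vertical astigmatism (Zernike Z(2,2)) amplitude in
#'   milli-lambda rms.
#' @param na numerical aperture.
#' @param n_imm immersion refractive index.
#' @param lambda emission wavelength (nm).
#' @param pixel_nm camera pixel size (nm).
#' @param half_size the stack covers `2*half_size+1` pixels laterally.
#' @param oversample sub-pixel sampling factor for pixel integration.
#' @return 3D array `[y, x, z]`, normalized so the central slice sums to 1.
#' @export
pupil_psf_stack <- function(z_positions, defocus_offset = 0,
                            sph_mlambda = 0, ast_mlambda = 0,
                            na = 1.43, n_imm = 1.518, lambda = 668,
                            pixel_nm = 100, half_size = 13, oversample = 2) {
  px <- pixel_nm / oversample
  Ngrid <- 128L
  dk <- 1 / (Ngrid * px)
  kx <- c(0:(Ngrid / 2 - 1), -(Ngrid / 2):-1) * dk
  KX <- matrix(kx, Ngrid, Ngrid)
  KY <- t(KX)
  KR2 <- KX^2 + KY^2
  kmax <- na / lambda
  pupil <- KR2 <= kmax^2
  kz <- sqrt(pmax((n_imm / lambda)^2 - KR2, 0))
  rho2 <- pmin(KR2 / kmax^2, 1)
  zern_sph <- sqrt(5) * (6 * rho2^2 - 6 * rho2 + 1)
  zern_ast <- sqrt(6) * (KX^2 - KY^2) / kmax^2
  phi_ab <- 2 * pi * (sph_mlambda * zern_sph + ast_mlambda * zern_ast) / 1000
  n_out <- 2L * half_size + 1L
  ctr <- Ngrid / 2 + 1L
  sel <- (ctr - oversample * half_size - (oversample - 1L)):
    (ctr + oversample * half_size)
  shift_idx <- c((Ngrid / 2 + 1L):Ngrid, 1:(Ngrid / 2))
  out <- array(0, c(n_out, n_out, length(z_positions)))
  for (i in seq_along(z_positions)) {
    z <- z_positions[i] + defocus_offset
    P <- pupil * exp(1i * (2 * pi * kz * z + phi_ab))
    I <- Mod(stats::fft(P))^2
    I <- I[shift_idx, shift_idx]
    big <- I[sel, sel]
    m <- matrix(0, n_out, n_out)
    for (a in seq_len(oversample)) for (b in seq_len(oversample))
      m <- m + big[seq(a, by = oversample, length.out = n_out),
                   seq(b, by = oversample, length.out = n_out)]
    out[, , i] <- m
  }
  out / sum(out[, , (length(z_positions) + 1) %/% 2])
}

#' Default spline biplane PSF pair from the scalar-diffraction model
#'
#' Two channels focused `plane_distance` apart, each rendered with a mild
#' spherical aberration and converted to a spline PSF. This is the default
#' stand-in for an experimental biplane calibration: the aberrated,
#' z-asymmetric shape keeps z identifiable in a single channel (weakly)
#' while the plane pairing encodes z strongly, reproducing the information
#' structure of bead-calibrated biplane PSFs.
#'
#' @param plane_distance axial separation of the focal planes (nm).
#' @param sph_mlambda spherical aberration per channel (mlambda rms).
#' @param z_range covered axial range (nm).
#' @param z_step stack spacing (nm).
#' @param ... passed to [pupil_psf_stack()].
#' @return list of two `cspline_psf` models.
#' @export
make_biplane_spline_psfs <- function(plane_distance = 400, sph_mlambda = 100,
                                     z_range = c(-800, 800), z_step = 25,
                                     ...) {
  zs <- seq(z_range[1], z_range[2], by = z_step)
  lapply(c(-1, 1) * plane_distance / 2, function(f) {
    stack <- pupil_psf_stack(zs, defocus_offset = f,
                             sph_mlambda = sph_mlambda, ...)
    fit_cspline(stack, z_step = z_step)
  })
}
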