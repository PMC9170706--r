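# Pixel-integrated astigmatic Gaussian PSF with the standard polynomial
# z-dependence of the widths. Used both as a parametric fitting model and as
# the generating model for synthetic data.

#' Astigmatic Gaussian PSF model
#'
#' The lateral profile is a Gaussian integrated over each camera pixel, with
#' z-dependent widths
#' \deqn{\sigma(z) = \sigma_0 \sqrt{1 + u^2 + A u^3 + B u^4}, \quad
#'       u = (z - \gamma)/d,}
#' where `gamma` is the focal offset of the axis (astigmatism gives the x and
#' y axes offsets of opposite sign) and `d` the depth of focus. All axial
#' quantities are in nanometers, lateral ones in camera pixels.
#'
#' @param sigma0 focal widths `c(sx, sy)` in pixels.
#' @param gamma focal offsets `c(gx, gy)` in nm.
#' @param d depth of focus in nm.
#' @param A,B optional higher-order coefficients, length-2 each.
#' @param z_range valid axial range `c(zmin, zmax)` in nm.
#' @return an object of class `c("gaussian_psf", "psf_model")`.
#' @export
gaussian_psf <- function(sigma0 = c(1.1, 1.1), gamma = c(180, -180), d = 350,
                         A = c(0, 0), B = c(0, 0), z_range = c(-800, 800)) {
  stopifnot(length(sigma0) == 2, all(sigma0 > 0), length(gamma) == 2, d > 0)
  obj <- list(sigma0 = sigma0, gamma = gamma, d = d,
              A = rep_len(A, 2), B = rep_len(B, 2), z_range = z_range)
  class(obj) <- c("gaussian_psf", "psf_model")
  obj
}

#' @export
psf_param_names <- function(psf) UseMethod("psf_param_names")
#' @export
psf_param_names.psf_model <- function(psf) c("x", "y", "z", "N", "bg")

#' @export
psf_z_range <- function(psf) UseMethod("psf_z_range")
#' @export
psf_z_range.gaussian_psf <- function(psf) psf$z_range

#' Gaussian width profile and its axial derivative
#'
#' @param psf a [gaussian_psf()].
#' @param z axial positions (nm).
#' @param axis 1 for x, 2 for y.
#' @return list with `sigma` and `dsigma_dz`.
#' @export
gaussian_sigma_z <- function(psf, z, axis) {
  u <- (z - psf$gamma[axis]) / psf$d
  s <- 1 + u^2 + psf$A[axis] * u^3 + psf$B[axis] * u^4
  if (any(s <= 0)) stop("sigma(z)^2 became non-positive inside the stated z range")
  sig <- psf$sigma0[axis] * sqrt(s)
  ds <- psf$sigma0[axis] * (2 * u + 3 * psf$A[axis] * u^2 + 4 * psf$B[axis] * u^3) /
    (2 * sqrt(s) * psf$d)
  list(sigma = sig, dsigma_dz = ds)
}

# 1D pixel-integrated Gaussian centered at x0 with width sigma, evaluated at
# integer pixel positions u. Returns value and derivatives wrt x0 and sigma.
pixgauss_1d <- function(u, x0, sigma) {
  ap <- (u - x0 + 0.5) / sigma
  am <- (u - x0 - 0.5) / sigma
  val <- stats::pnorm(ap) - stats::pnorm(am)
  dp <- stats::dnorm(ap)
  dm <- stats::dnorm(am)
  list(
    val = val,
    dx = -(dp - dm) / sigma,
    dsigma = -(ap * dp - am * dm) / sigma
  )
}

# Core evaluation: normalized PSF values (sum over the infinite plane = 1)
# and derivatives wrt x, y, z on an roi_size x roi_size grid.
# Returns list(val, dval) with dval columns x, y, z; vectors follow R's
# column-major matrix layout (y fastest).
psf_eval_raw <- function(psf, x, y, z, roi_size, chan = 1L, ...) UseMethod("psf_eval_raw")

psf_eval_raw.gaussian_psf <- function(psf, x, y, z, roi_size, chan = 1L, ...) {
  zr <- psf$z_range
  if (z < zr[1] || z > zr[2])
    stop("z = ", z, " nm outside the calibrated range [", zr[1], ", ", zr[2], "]")
  sx <- gaussian_sigma_z(psf, z, 1)
  sy <- gaussian_sigma_z(psf, z, 2)
  u <- 0:(roi_size - 1)
  gx <- pixgauss_1d(u, x, sx$sigma)
  gy <- pixgauss_1d(u, y, sy$sigma)
  # matrix [row = y, col = x]
  val <- outer(gy$val, gx$val)
  dvx <- outer(gy$val, gx$dx)
  dvy <- outer(gy$dx, gx$val)
  dvz <- outer(gy$val, gx$dsigma) * sx$dsigma_dz +
    outer(gy$dsigma, gx$val) * sy$dsigma_dz
  list(val = as.vector(val),
       dval = cbind(x = as.vector(dvx), y = as.vector(dvy), z = as.vector(dvz)))
}
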