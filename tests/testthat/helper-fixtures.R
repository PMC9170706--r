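# Shared fixtures, built in code. Kept deliberately small: unit tests use
# few molecules and short z grids; the full-scale simulation benchmarks
# live in test-acceptance.R.

tiny_gauss_psf <- function(...) {
  gaussian_psf(sigma0 = c(1.2, 1.2), gamma = c(180, -180), d = 350,
               z_range = c(-600, 600), ...)
}

# small spline PSF sampled from an analytic Gaussian model
tiny_cspline_psf <- function(z_step = 40, half = 10) {
  g <- tiny_gauss_psf()
  zs <- seq(-400, 400, by = z_step)
  n <- 2 * half + 1
  stack <- array(0, c(n, n, length(zs)))
  for (k in seq_along(zs))
    stack[, , k] <- matrix(psf_eval_raw_for_test(g, half, half, zs[k], n), n, n)
  fit_cspline(stack, z_step = z_step)
}

# evaluate a PSF's normalized profile via the public API
psf_eval_raw_for_test <- function(psf, x, y, z, roi_size) {
  evaluate_channel(psf, list(x = x, y = y, z = z, N = 1, bg = 0), roi_size)
}

# central finite difference of evaluate_channel wrt one parameter
fd_derivative <- function(psf, params, roi_size, name, h, channel = 1L) {
  pp <- params; pm <- params
  pp[[name]] <- pp[[name]] + h
  pm[[name]] <- pm[[name]] - h
  (evaluate_channel(psf, pp, roi_size, channel = channel) -
     evaluate_channel(psf, pm, roi_size, channel = channel)) / (2 * h)
}

fd_steps <- c(x = 1e-3, y = 1e-3, z = 1e-2, N = 1e-1, bg = 1e-3, phi = 1e-4)

expect_rel_close <- function(a, b, tol, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(b))
  expect_lt(max(abs(a - b)) / scale, tol)
}
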