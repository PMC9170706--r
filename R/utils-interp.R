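# Shared low-level image utilities: cubic convolution interpolation,
# sub-pixel shifting, FFT cross-correlation and local-maximum finding.
# Conventions: images are matrices indexed [row = y, col = x]; pixel centers
# sit at integer coordinates, 0-based, so image[1, 1] is the pixel at (0, 0).

#' Cubic convolution (Catmull-Rom) interpolation weights
#'
#' Weights for the four samples at offsets -1, 0, 1, 2 around the
#' integer part of the query, for fractional position `t` in \[0, 1).
#' The kernel interpolates the samples and is C1 continuous.
#'
#' @param t numeric vector of fractional positions in \[0, 1\].
#' @return a length(t) x 4 matrix of weights.
#' @keywords internal
cubic_weights <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  cbind(
    -0.5 * t3 + t2 - 0.5 * t,
    1.5 * t3 - 2.5 * t2 + 1,
    -1.5 * t3 + 2 * t2 + 0.5 * t,
    0.5 * t3 - 0.5 * t2
  )
}

# Sample a vector at arbitrary (0-based) positions by cubic convolution with
# replicated (clamped) edges.
cubic_sample_1d <- function(v, pos) {
  n <- length(v)
  i0 <- floor(pos)
  t <- pos - i0
  w <- cubic_weights(t)
  out <- numeric(length(pos))
  for (m in 0:3) {
    idx <- pmin(pmax(i0 + m - 1L, 0), n - 1L) + 1L
    out <- out + w[, m + 1L] * v[idx]
  }
  out
}

# Interpolation matrix W (length(pos) x n) such that W %*% v == cubic_sample_1d(v, pos).
cubic_interp_matrix <- function(n, pos) {
  i0 <- floor(pos)
  t <- pos - i0
  w <- cubic_weights(t)
  W <- matrix(0, length(pos), n)
  for (m in 0:3) {
    idx <- pmin(pmax(i0 + m - 1L, 0), n - 1L) + 1L
    W[cbind(seq_along(pos), idx)] <- W[cbind(seq_along(pos), idx)] + w[, m + 1L]
  }
  W
}

#' Shift a 2D image by a sub-pixel amount using cubic interpolation
#'
#' The output samples the input at `x + sx`, `y + sy`; image content
#' therefore moves by `(-sx, -sy)`. Edges are replicated.
#'
#' @param img matrix \[y, x\].
#' @param sx,sy shift in pixels along x (columns) and y (rows).
#' @return shifted matrix of the same size.
#' @export
cubic_shift_image <- function(img, sx, sy) {
  ny <- nrow(img); nx <- ncol(img)
  Wy <- cubic_interp_matrix(ny, (0:(ny - 1)) + sy)
  Wx <- cubic_interp_matrix(nx, (0:(nx - 1)) + sx)
  Wy %*% img %*% t(Wx)
}

#' Shift a 3D stack by sub-voxel amounts using separable cubic interpolation
#'
#' @param arr 3D array \[y, x, z\].
#' @param s shift c(sx, sy, sz) in voxels; output samples input at `pos + s`.
#' @return shifted array of the same size.
#' @export
cubic_shift_3d <- function(arr, s) {
  d <- dim(arr)
  Wy <- cubic_interp_matrix(d[1], (0:(d[1] - 1)) + s[2])
  Wx <- cubic_interp_matrix(d[2], (0:(d[2] - 1)) + s[1])
  Wz <- cubic_interp_matrix(d[3], (0:(d[3] - 1)) + s[3])
  # apply along y, then x, then z via matrix products on unfolded arrays
  m <- matrix(arr, d[1], d[2] * d[3])
  arr <- array(Wy %*% m, c(d[1], d[2], d[3]))
  arr <- aperm(arr, c(2, 1, 3))
  m <- matrix(arr, d[2], d[1] * d[3])
  arr <- array(Wx %*% m, c(d[2], d[1], d[3]))
  arr <- aperm(arr, c(2, 1, 3))
  m <- matrix(arr, d[1] * d[2], d[3])
  array(m %*% t(Wz), d)
}

# Gaussian blur with replicated borders (EBImage backend).
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(3L, 2L * as.integer(ceiling(3 * sigma)) + 1L)
  r <- min(r, 2L * (min(dim(img)) %/% 2L) - 1L)
  if (r < 3L) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = r, boundary = "replicate"))
}

#' Cross-correlation of two equally sized arrays via FFT
#'
#' Computes `c(delta) = sum_x a(x) * b(x + delta)` with zero padding
#' (linear, not circular, correlation). If `b` equals `a` with its content
#' moved by `+d`, the correlation peaks at `delta = d`.
#'
#' @param a,b arrays (2D or 3D) of identical dimensions.
#' @return list with `corr` (array of size 2*dim-1) and `lags` (list of
#'   per-axis integer lag vectors matching the dimensions of `corr`).
#' @keywords internal
xcorr_fft <- function(a, b) {
  d <- dim(a)
  stopifnot(identical(d, dim(b)))
  dp <- 2L * d - 1L
  ix <- lapply(d, seq_len)
  pa <- array(0, dp); pb <- array(0, dp)
  pa <- do.call(`[<-`, c(list(pa), ix, list(a)))
  pb <- do.call(`[<-`, c(list(pb), ix, list(b)))
  cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE)) / prod(dp)
  # lag along each axis: 0, 1, ..., d-1, -(d-1), ..., -1
  lags <- lapply(d, function(n) c(0:(n - 1L), -((n - 1L):1L)))
  # reorder to ascending lags -(d-1) .. (d-1)
  ord <- lapply(lags, order)
  cc <- do.call(`[`, c(list(cc), ord, list(drop = FALSE)))
  lags <- lapply(seq_along(lags), function(k) lags[[k]][ord[[k]]])
  list(corr = cc, lags = lags)
}

# Sub-voxel refinement of a correlation peak: crop a neighborhood around the
# integer peak, lightly Gaussian-smooth (2D only), then cubic-interpolate on an
# `upscale`-times finer grid and take the brightest sample.
refine_peak_subpixel <- function(corr, lags, upscale = 4L, halfwidth = 3L,
                                 smooth_sigma = 0) {
  d <- dim(corr)
  imax <- arrayInd(which.max(corr), d)[1, ]
  nd <- length(d)
  # cropped coordinate windows (clamped to the array)
  win <- lapply(seq_len(nd), function(k) {
    lo <- max(1L, imax[k] - halfwidth); hi <- min(d[k], imax[k] + halfwidth)
    lo:hi
  })
  crop <- do.call(`[`, c(list(corr), win, list(drop = FALSE)))
  if (smooth_sigma > 0 && nd == 2L && all(dim(crop) >= 3L))
    crop <- gauss_blur(crop, smooth_sigma)
  # fine grids (0-based within the crop)
  step <- 1 / upscale
  fine <- lapply(seq_len(nd), function(k) seq(0, length(win[[k]]) - 1L, by = step))
  Ws <- lapply(seq_len(nd), function(k) cubic_interp_matrix(length(win[[k]]), fine[[k]]))
  up <- crop
  if (nd == 2L) {
    up <- Ws[[1]] %*% crop %*% t(Ws[[2]])
  } else {
    dd <- dim(crop)
    m <- matrix(crop, dd[1], dd[2] * dd[3])
    up <- array(Ws[[1]] %*% m, c(nrow(Ws[[1]]), dd[2], dd[3]))
    up <- aperm(up, c(2, 1, 3))
    m <- matrix(up, dd[2], prod(dim(up)[-1]))
    up <- array(Ws[[2]] %*% m, c(nrow(Ws[[2]]), nrow(Ws[[1]]), dd[3]))
    up <- aperm(up, c(2, 1, 3))
    m <- matrix(up, prod(dim(up)[1:2]), dd[3])
    up <- array(m %*% t(Ws[[3]]), c(nrow(Ws[[1]]), nrow(Ws[[2]]), nrow(Ws[[3]])))
  }
  fmax <- arrayInd(which.max(up), dim(up))[1, ]
  vapply(seq_len(nd), function(k) {
    lags[[k]][win[[k]][1]] + fine[[k]][fmax[k]]
  }, numeric(1))
}

# Strict local maxima of a matrix above a threshold. Plateau ties are broken
# lexicographically: a pixel qualifies if it is >= all 8 neighbours and
# strictly greater than every neighbour with a smaller (row, col) index.
local_maxima <- function(img, threshold = -Inf) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- img
  ctr <- pad[2:(ny + 1L), 2:(nx + 1L)]
  ok <- ctr > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
    # lexicographic order on (col, row) treating x as major axis is irrelevant;
    # use (row, col): neighbour earlier if dy < 0, or dy == 0 and dx < 0
    earlier <- dy < 0 || (dy == 0 && dx < 0)
    ok <- ok & (if (earlier) ctr > nb else ctr >= nb)
  }
  which(ok, arr.ind = TRUE)
}

wrap_phase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}
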