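# Tricubic-spline PSF: a piecewise tricubic interpolant of a (registered,
# averaged, normalized) experimental bead stack. Coefficients are built per
# voxel from function values and central-difference derivatives at the voxel
# corners (separable Catmull-Rom construction), which interpolates the stack
# at its samples and is C1 across voxel boundaries. Boundary voxels use
# replicated neighbours; evaluation outside the lateral support is clamped to
# the edge, evaluation outside the axial range is an error.

# 4x4 basis-conversion matrix: p(t) = [1 t t^2 t^3] %*% CR %*% f[-1..2]
catmull_rom_matrix <- function() {
  0.5 * matrix(c(
    0, 2, 0, 0,
    -1, 0, 1, 0,
    2, -5, 4, -1,
    -1, 3, -3, 1
  ), 4, 4, byrow = TRUE)
}

#' Fit a tricubic spline PSF to a sampled stack
#'
#' @param stack 3D array `[y, x, z]` of normalized PSF values; at least 4
#'   samples along each axis.
#' @param z_step nm per z slice.
#' @param z0_index slice index (1-based) corresponding to z = 0; defaults to
#'   the central slice.
#' @param normalization scalar recorded from the calibration (sum of the
#'   central reference slice); informational.
#' @return an object of class `c("cspline_psf", "psf_model")`.
#' @export
fit_cspline <- function(stack, z_step = 10, z0_index = NULL, normalization = 1) {
  d <- dim(stack)
  if (length(d) != 3 || any(d < 4))
    stop("stack must be 3D with at least 4 samples along each axis")
  if (!all(is.finite(stack))) stop("stack contains non-finite values")
  if (is.null(z0_index)) z0_index <- (d[3] + 1) / 2
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  nvy <- ny - 1L; nvx <- nx - 1L; nvz <- nz - 1L
  A <- catmull_rom_matrix()
  # K[(a,b,c),(m,n,o)] with x fastest in both: powers (tx^a ty^b tz^c),
  # neighbours (x offset m, y offset n, z offset o)
  K <- (A %x% A) %x% A # slow factor = z, fast = x
  # gather 4x4x4 neighbourhoods for every voxel into F (nvox x 64)
  vy <- rep(seq_len(nvy), times = nvx * nvz)
  vx <- rep(rep(seq_len(nvx), each = nvy), times = nvz)
  vz <- rep(seq_len(nvz), each = nvy * nvx)
  nvox <- nvy * nvx * nvz
  Fm <- matrix(0, nvox, 64L)
  col <- 1L
  for (o in 0:3) {
    zi <- pmin(pmax(vz + o - 1L, 1L), nz)
    for (n in 0:3) {
      yi <- pmin(pmax(vy + n - 1L, 1L), ny)
      for (m in 0:3) {
        xi <- pmin(pmax(vx + m - 1L, 1L), nx)
        Fm[, col] <- stack[cbind(yi, xi, zi)]
        col <- col + 1L
      }
    }
  }
  # column index of Fm is m + 4n + 16o + 1 -> matches K's fast-x layout
  coef <- Fm %*% t(K)
  obj <- list(
    coef = coef, dim = c(ny = ny, nx = nx, nz = nz),
    z_step = z_step, z0_index = z0_index, lateral_step = 1,
    normalization = normalization,
    center = c(x = (nx - 1) / 2, y = (ny - 1) / 2),
    powers = list(
      a = rep(0:3, times = 16L),
      b = rep(rep(0:3, each = 4L), times = 4L),
      c = rep(0:3, each = 16L)
    )
  )
  class(obj) <- c("cspline_psf", "psf_model")
  obj
}

#' @export
psf_z_range.cspline_psf <- function(psf) {
  nz <- psf$dim[["nz"]]
  (c(1, nz) - psf$z0_index) * psf$z_step
}

# Evaluate the spline (and optionally derivatives) at spline-grid coordinates
# xs, ys (0-based sample units) and a scalar zs. Lateral clamping replicates
# the edge; zs must lie within the grid.
cspline_eval_grid <- function(psf, xs, ys, zs, derivatives = TRUE) {
  ny <- psf$dim[["ny"]]; nx <- psf$dim[["nx"]]; nz <- psf$dim[["nz"]]
  if (zs < 0 || zs > nz - 1)
    stop("z outside the calibrated range of the spline PSF")
  eps <- 1e-9
  clx <- xs < 0 | xs > nx - 1
  cly <- ys < 0 | ys > ny - 1
  xs <- pmin(pmax(xs, 0), nx - 1 - eps)
  ys <- pmin(pmax(ys, 0), ny - 1 - eps)
  zs <- min(max(zs, 0), nz - 1 - eps)
  ix <- pmin(floor(xs), nx - 2); tx <- xs - ix
  iy <- pmin(floor(ys), ny - 2); ty <- ys - iy
  iz <- min(floor(zs), nz - 2); tz <- zs - iz
  npt <- length(xs)
  # voxel (linear) index per point; coef rows are ordered y-fastest, then x, z
  vrow <- (iy + 1L) + ix * (ny - 1L) + iz * (ny - 1L) * (nx - 1L)
  C <- psf$coef[vrow, , drop = FALSE]
  pw <- psf$powers
  # fast path: ROI grids share one fractional offset per axis, so a single
  # 64-element basis vector serves every pixel
  if (npt > 1 && max(tx) - min(tx) < 1e-12 && max(ty) - min(ty) < 1e-12) {
    t1 <- tx[1]; t2 <- ty[1]
    px <- c(1, t1, t1^2, t1^3); py <- c(1, t2, t2^2, t2^3)
    pz <- c(1, tz, tz^2, tz^3)
    ia <- pw$a + 1L; ib <- pw$b + 1L; ic <- pw$c + 1L
    if (!derivatives)
      return(list(val = as.vector(C %*% (px[ia] * py[ib] * pz[ic]))))
    pxd <- c(0, 1, 2 * t1, 3 * t1^2); pyd <- c(0, 1, 2 * t2, 3 * t2^2)
    pzd <- c(0, 1, 2 * tz, 3 * tz^2)
    B <- cbind(px[ia] * py[ib] * pz[ic],
               pxd[ia] * py[ib] * pz[ic],
               px[ia] * pyd[ib] * pz[ic],
               px[ia] * py[ib] * pzd[ic])
    out <- C %*% B
    return(list(val = out[, 1], dtx = out[, 2], dty = out[, 3],
                dtz = out[, 4]))
  }
  TX <- cbind(1, tx, tx^2, tx^3)
  TY <- cbind(1, ty, ty^2, ty^3)
  TZv <- c(1, tz, tz^2, tz^3)
  TXd <- cbind(0, 1, 2 * tx, 3 * tx^2)
  TYd <- cbind(0, 1, 2 * ty, 3 * ty^2)
  TZd <- c(0, 1, 2 * tz, 3 * tz^2)
  B <- TX[, pw$a + 1L, drop = FALSE] * TY[, pw$b + 1L, drop = FALSE] *
    rep(TZv[pw$c + 1L], each = npt)
  val <- rowSums(C * B)
  if (!derivatives) return(list(val = val))
  Bx <- TXd[, pw$a + 1L, drop = FALSE] * TY[, pw$b + 1L, drop = FALSE] *
    rep(TZv[pw$c + 1L], each = npt)
  By <- TX[, pw$a + 1L, drop = FALSE] * TYd[, pw$b + 1L, drop = FALSE] *
    rep(TZv[pw$c + 1L], each = npt)
  Bz <- TX[, pw$a + 1L, drop = FALSE] * TY[, pw$b + 1L, drop = FALSE] *
    rep(TZd[pw$c + 1L], each = npt)
  dtx <- rowSums(C * Bx); dtx[clx] <- 0
  dty <- rowSums(C * By); dty[cly] <- 0
  list(val = val, dtx = dtx, dty = dty, dtz = rowSums(C * Bz))
}

psf_eval_raw.cspline_psf <- function(psf, x, y, z, roi_size, chan = 1L, ...) {
  zr <- psf_z_range(psf)
  if (z < zr[1] || z > zr[2])
    stop("z = ", z, " nm outside the calibrated range [", zr[1], ", ", zr[2], "]")
  u <- 0:(roi_size - 1)
  # molecule at (x, y) in ROI coords; spline center maps to the molecule
  xs <- rep(u - x + psf$center[["x"]], each = roi_size)
  ys <- rep(u - y + psf$center[["y"]], times = roi_size)
  zs <- z / psf$z_step + (psf$z0_index - 1)
  ev <- cspline_eval_grid(psf, xs, ys, zs, derivatives = TRUE)
  neg <- ev$val < 0
  val <- ev$val
  if (any(neg)) { # clamp undershoot to 0 and keep derivatives consistent
    val[neg] <- 0
    ev$dtx[neg] <- 0; ev$dty[neg] <- 0; ev$dtz[neg] <- 0
  }
  list(val = val,
       dval = cbind(x = -ev$dtx, y = -ev$dty, z = ev$dtz / psf$z_step))
}
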