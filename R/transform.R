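# Inter-channel geometric registration from point sets (bead or single
# molecule coordinates): bootstrap translation by binned cross-correlation,
# iterative linking of mutual nearest neighbours within a shrinking search
# radius, and a least-squares projective / affine / polynomial fit on the
# linked anchor points.

#' Projective transform between detection channels
#'
#' @param matrix 3x3 homogeneous matrix mapping reference coordinates to
#'   target coordinates (pixels).
#' @param mirror_axis `"none"`, `"x"` or `"y"`: declares that the target
#'   channel image is mirrored along that axis; the coordinate reflection
#'   itself is part of `matrix`, the flag tells ROI extraction to flip
#'   pixel data.
#' @return object of class `channel_transform`.
#' @export
channel_transform <- function(matrix, mirror_axis = c("none", "x", "y")) {
  mirror_axis <- match.arg(mirror_axis)
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
  if (!is.finite(rcond(matrix)) || rcond(matrix) < 1e-12)
    stop("transform matrix is singular")
  obj <- list(matrix = matrix / matrix[3, 3], inverse = solve(matrix),
              mirror_axis = mirror_axis)
  obj$inverse <- obj$inverse / obj$inverse[3, 3]
  class(obj) <- "channel_transform"
  obj
}

#' Identity channel transform
#' @export
identity_transform <- function() channel_transform(diag(3))

#' Invert a channel transform
#' @param tf a [channel_transform()].
#' @export
invert_transform <- function(tf) {
  channel_transform(tf$inverse, mirror_axis = tf$mirror_axis)
}

#' Apply a channel transform to points
#'
#' Homogeneous multiply followed by dehomogenization.
#'
#' @param tf a [channel_transform()].
#' @param points n x 2 matrix (or data.frame with columns x, y).
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(tf, points) {
  xy <- as_xy(points)
  h <- tf$matrix %*% rbind(t(xy), 1)
  w <- h[3, ]
  if (any(abs(w) < 1e-12))
    stop("point maps to the plane at infinity (w ~ 0)")
  cbind(x = h[1, ] / w, y = h[2, ] / w)
}

as_xy <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  stopifnot(ncol(points) == 2, all(is.finite(points)))
  points
}

#' Bin point coordinates into a super-pixel count image
#'
#' @param points data.frame with `x`, `y` (or n x 2 matrix), in the same
#'   units as `pixel_size`.
#' @param pixel_size super-pixel size (e.g. 50 nm, or 0.5 px for
#'   pixel-unit coordinates).
#' @param origin optional `c(x0, y0)` lower corner of the binning grid;
#'   defaults to the floor of the point minimum. Pass a shared origin and
#'   `dims` to bin two point sets onto one grid.
#' @param dims optional `c(nx, ny)` number of bins.
#' @return matrix of counts `[row = y bin, col = x bin]`; the sum equals
#'   the number of points.
#' @export
bin_superpixels <- function(points, pixel_size, origin = NULL, dims = NULL) {
  xy <- as_xy(points)
  if (nrow(xy) == 0) stop("empty point set")
  stopifnot(pixel_size > 0)
  if (is.null(origin)) origin <- c(min(xy[, 1]), min(xy[, 2]))
  ix <- floor((xy[, 1] - origin[1]) / pixel_size)
  iy <- floor((xy[, 2] - origin[2]) / pixel_size)
  if (is.null(dims)) dims <- c(max(ix) + 1L, max(iy) + 1L)
  keep <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2]
  img <- matrix(0, dims[2], dims[1])
  if (any(keep)) {
    t1 <- table(factor(iy[keep] + 1L, levels = seq_len(dims[2])),
                factor(ix[keep] + 1L, levels = seq_len(dims[1])))
    img <- img + unclass(t1)
  }
  attr(img, "origin") <- origin
  attr(img, "pixel_size") <- pixel_size
  img
}

#' Sub-pixel shift between two images by upscaled cross-correlation
#'
#' Cross-correlates the mean-subtracted images, then refines the brightest
#' correlation pixel on an `upscale`-times finer grid obtained by light
#' Gaussian filtering and cubic interpolation.
#'
#' @param image_a,image_b equally sized matrices.
#' @param upscale integer upscaling factor (default 4).
#' @return `c(dx, dy)` such that `image_b` matches `image_a` with its
#'   content moved by `(dx, dy)` pixels.
#' @export
estimate_shift_xcorr <- function(image_a, image_b, upscale = 4L) {
  stopifnot(identical(dim(image_a), dim(image_b)))
  if (stats::sd(image_a) == 0 || stats::sd(image_b) == 0)
    stop("degenerate (constant) image: correlation undefined")
  a <- image_a - mean(image_a)
  b <- image_b - mean(image_b)
  xc <- xcorr_fft(a, b)
  pk <- refine_peak_subpixel(xc$corr, xc$lags, upscale = upscale,
                             halfwidth = 3L, smooth_sigma = 1 / upscale)
  # lags are (row = y, col = x); report (dx, dy)
  c(dx = pk[2], dy = pk[1])
}

#' Link reference and target points within a search radius
#'
#' Target points are first mapped back to the reference channel by the
#' inverse of `T0`; a reference and a target point are linked when they are
#' mutual nearest neighbours closer than `rho` (and, when frame indices are
#' present, lie in the same frame). Each point is used at most once.
#'
#' @param ref,target data.frames with `x`, `y` and optionally `frame`.
#' @param T0 approximate [channel_transform()] (default identity).
#' @param rho maximum link distance (reference pixels).
#' @return data.frame with `ref_index`, `target_index`, `distance`.
#' @export
link_points <- function(ref, target, T0 = NULL, rho) {
  stopifnot(rho > 0)
  if (is.null(T0)) T0 <- identity_transform()
  txy <- apply_transform(invert_transform(T0), target)
  rxy <- as_xy(ref)
  rframe <- if (!is.null(ref$frame)) ref$frame else rep(0L, nrow(rxy))
  tframe <- if (!is.null(target$frame)) target$frame else rep(0L, nrow(txy))
  out <- list()
  for (f in intersect(unique(rframe), unique(tframe))) {
    ri <- which(rframe == f); ti <- which(tframe == f)
    if (!length(ri) || !length(ti)) next
    D <- outer(rxy[ri, 1], txy[ti, 1], `-`)^2 +
      outer(rxy[ri, 2], txy[ti, 2], `-`)^2
    D <- sqrt(D)
    nn_t <- apply(D, 1, which.min)   # nearest target for each ref
    nn_r <- apply(D, 2, which.min)   # nearest ref for each target
    mutual <- which(nn_r[nn_t] == seq_along(ri))
    d <- D[cbind(mutual, nn_t[mutual])]
    keep <- d < rho
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        ref_index = ri[mutual[keep]],
        target_index = ti[nn_t[mutual[keep]]],
        distance = d[keep])
  }
  if (!length(out))
    return(data.frame(ref_index = integer(0), target_index = integer(0),
                      distance = numeric(0)))
  do.call(rbind, out)
}

#' Least-squares transform from matched anchor points
#'
#' Projective fits use the normalized direct linear transform; affine and
#' polynomial (degree 2) fits use linear least squares. Polynomial
#' transforms are returned as an affine `channel_transform` approximation
#' plus the full coefficient set in the `poly` attribute.
#'
#' @param ref_xy,target_xy matched coordinates (n x 2).
#' @param kind `"projective"`, `"affine"` or `"polynomial"`.
#' @return a [channel_transform()] with attribute `residual_rms` (pixels).
#' @export
fit_transform <- function(ref_xy, target_xy, kind = c("projective", "affine",
                                                      "polynomial")) {
  kind <- match.arg(kind)
  r <- as_xy(ref_xy); t <- as_xy(target_xy)
  stopifnot(nrow(r) == nrow(t))
  n <- nrow(r)
  min_n <- switch(kind, projective = 4L, affine = 3L, polynomial = 6L)
  if (n < min_n) stop("need at least ", min_n, " anchor pairs for ", kind)
  check_rank <- function(xy) {
    s <- svd(cbind(xy[, 1] - mean(xy[, 1]), xy[, 2] - mean(xy[, 2])))$d
    if (s[2] < 1e-9 * max(s[1], 1))
      stop("anchor points are collinear/degenerate")
  }
  check_rank(r); check_rank(t)
  if (kind == "affine" || kind == "polynomial") {
    X <- if (kind == "affine") cbind(1, r)
         else cbind(1, r, r[, 1]^2, r[, 1] * r[, 2], r[, 2]^2)
    cf <- qr.coef(qr(X), t)
    pred <- X %*% cf
    A <- diag(3)
    A[1, ] <- c(cf[2, 1], cf[3, 1], cf[1, 1])
    A[2, ] <- c(cf[2, 2], cf[3, 2], cf[1, 2])
    tf <- channel_transform(A)
    if (kind == "polynomial") attr(tf, "poly") <- cf
  } else {
    # normalized DLT
    normalize <- function(xy) {
      c0 <- colMeans(xy)
      sc <- sqrt(2) / mean(sqrt(rowSums(sweep(xy, 2, c0)^2)))
      Tm <- matrix(c(sc, 0, -sc * c0[1], 0, sc, -sc * c0[2], 0, 0, 1),
                   3, 3, byrow = TRUE)
      list(Tm = Tm, xy = cbind(sc * (xy[, 1] - c0[1]), sc * (xy[, 2] - c0[2])))
    }
    nr <- normalize(r); nt <- normalize(t)
    x <- nr$xy[, 1]; y <- nr$xy[, 2]; u <- nt$xy[, 1]; v <- nt$xy[, 2]
    Z <- rep(0, n); O <- rep(1, n)
    A <- rbind(
      cbind(x, y, O, Z, Z, Z, -u * x, -u * y, -u),
      cbind(Z, Z, Z, x, y, O, -v * x, -v * y, -v))
    sv <- svd(A)
    if (sv$d[8] < 1e-9 * sv$d[1])
      stop("anchor configuration is degenerate for a projective fit")
    h <- sv$v[, 9]
    Hn <- matrix(h, 3, 3, byrow = TRUE)
    H <- solve(nt$Tm) %*% Hn %*% nr$Tm
    tf <- channel_transform(H)
    pred <- apply_transform(tf, r)
  }
  attr(tf, "residual_rms") <- sqrt(mean(rowSums((pred - t)^2)))
  tf
}

#' Estimate the transform between two channels from point sets
#'
#' Bootstraps a translation by super-pixel binning and cross-correlation
#' (unless `T0` is given), then alternates linking and least-squares
#' fitting over a decreasing radius schedule.
#'
#' @param ref,target point sets (data.frames with `x`, `y`, optional
#'   `frame`), coordinates in reference pixels.
#' @param rho_schedule decreasing link radii (pixels).
#' @param T0 optional starting transform.
#' @param kind transform family for [fit_transform()].
#' @param bin_size super-pixel size for the bootstrap, in point units
#'   (default 0.5 px = 50 nm at 100 nm pixels).
#' @return a [channel_transform()] with attribute `diagnostics`
#'   (per-iteration pair count and residual RMS).
#' @export
estimate_transform <- function(ref, target, rho_schedule = c(2, 0.5),
                               T0 = NULL, kind = "projective",
                               bin_size = 0.5) {
  rxy <- as_xy(ref); txy <- as_xy(target)
  if (nrow(rxy) == 0 || nrow(txy) == 0) stop("empty point set")
  if (is.null(T0)) {
    all_xy <- rbind(rxy, txy)
    origin <- c(min(all_xy[, 1]), min(all_xy[, 2])) - bin_size
    dims <- c(ceiling((max(all_xy[, 1]) - origin[1]) / bin_size) + 2L,
              ceiling((max(all_xy[, 2]) - origin[2]) / bin_size) + 2L)
    ia <- bin_superpixels(rxy, bin_size, origin, dims)
    ib <- bin_superpixels(txy, bin_size, origin, dims)
    sh <- estimate_shift_xcorr(ia, ib, upscale = 4L)
    A <- diag(3); A[1, 3] <- sh[1] * bin_size; A[2, 3] <- sh[2] * bin_size
    T0 <- channel_transform(A)
  }
  tf <- T0
  diag_rows <- list()
  history <- list()
  for (rho in rho_schedule) {
    pairs <- link_points(ref, target, tf, rho)
    if (nrow(pairs) < 4)
      stop("linkage failure: only ", nrow(pairs), " pairs at rho = ", rho)
    tf_new <- fit_transform(rxy[pairs$ref_index, , drop = FALSE],
                            txy[pairs$target_index, , drop = FALSE],
                            kind = kind)
    tf <- tf_new
    history[[length(history) + 1L]] <- tf_new
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      rho = rho, n_pairs = nrow(pairs),
      residual_rms = attr(tf_new, "residual_rms"))
  }
  attr(tf, "diagnostics") <- do.call(rbind, diag_rows)
  attr(tf, "history") <- history
  tf
}
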