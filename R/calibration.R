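# Multi-channel PSF calibration from bead z-stacks: candidate detection on
# the z-averaged image, transform-aware ROI cutting with sub-pixel residual
# shifts, iterative 3D registration and averaging with quality control,
# reference-channel normalization, axial smoothing and spline fitting. The
# residual-shift convention established here is the same one the fitter
# consumes, so the channels of the resulting model stay jointly registered.

#' Find candidate bead positions in a z-stack
#'
#' Beads are strict local maxima of the Gaussian-filtered z-mean image above
#' a threshold, at least `roi_size/2` pixels from the borders.
#'
#' @param stack 3D array `[y, x, z]` (photons).
#' @param threshold absolute threshold on the filtered mean image, or
#'   `NULL` to use `rel_threshold` times its robust maximum (0.999
#'   quantile).
#' @param rel_threshold relative threshold (default 0.2).
#' @param sigma Gaussian filter width (pixels).
#' @param roi_size lateral ROI size the positions must accommodate.
#' @return integer matrix with columns `x`, `y` (0-based pixel indices).
#' @export
find_bead_candidates <- function(stack, threshold = NULL, rel_threshold = 0.2,
                                 sigma = 1, roi_size = 27) {
  stopifnot(length(dim(stack)) == 3)
  mn <- apply(stack, c(1, 2), mean)
  flt <- gauss_blur(mn, sigma)
  if (is.null(threshold)) {
    stopifnot(rel_threshold > 0)
    threshold <- rel_threshold *
      (stats::quantile(flt, 0.999) - stats::median(flt)) + stats::median(flt)
  } else stopifnot(threshold > 0)
  pk <- local_maxima(flt, threshold)
  if (nrow(pk) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  half <- ceiling(roi_size / 2)
  ny <- nrow(flt); nx <- ncol(flt)
  keep <- pk[, "row"] > half & pk[, "row"] <= ny - half &
    pk[, "col"] > half & pk[, "col"] <= nx - half
  cbind(x = pk[keep, "col"] - 1L, y = pk[keep, "row"] - 1L)
}

# integer crop of a 3D stack: ROI of side roi_size centered on the 0-based
# pixel (cx, cy); returns NULL if out of bounds
crop_roi_3d <- function(stack, cx, cy, roi_size) {
  half <- (roi_size - 1) %/% 2
  rows <- (cy - half):(cy + roi_size - half - 1) + 1L
  cols <- (cx - half):(cx + roi_size - half - 1) + 1L
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > dim(stack)[1] || max(cols) > dim(stack)[2]) return(NULL)
  stack[rows, cols, , drop = FALSE]
}

mirror_stack <- function(arr, axis) {
  switch(axis,
         none = arr,
         x = arr[, dim(arr)[2]:1, , drop = FALSE],
         y = arr[dim(arr)[1]:1, , , drop = FALSE])
}

#' Cut co-registered bead ROIs from all channels
#'
#' The reference ROI is cut at the integer candidate position; each target
#' position is mapped through the channel transform, cut at the rounded
#' position and resampled by the residual shift `s` (cubic interpolation)
#' so the channels are co-centered. Mirrored channels are flipped before
#' shifting.
#'
#' @param stacks list of per-channel 3D arrays.
#' @param ref_positions integer matrix (x, y) of candidates in the
#'   reference channel.
#' @param transforms list of [channel_transform()] mapping reference to
#'   each target channel (`NULL` entries = identity; element 1 is the
#'   reference and is ignored).
#' @param roi_size lateral ROI side.
#' @return list of bead ROIs; each is a list with `channels` (list of 3D
#'   arrays), `shifts` (`n_channels x 2`), `position`.
#' @export
cut_shifted_rois <- function(stacks, ref_positions, transforms = NULL,
                             roi_size = 27) {
  nch <- length(stacks)
  ref_positions <- matrix(as.integer(ref_positions), ncol = 2)
  if (is.null(transforms)) transforms <- rep(list(identity_transform()), nch)
  out <- list()
  for (b in seq_len(nrow(ref_positions))) {
    xr <- ref_positions[b, ]
    chans <- vector("list", nch)
    shifts <- matrix(0, nch, 2)
    ok <- TRUE
    for (i in seq_len(nch)) {
      if (i == 1L) {
        roi <- crop_roi_3d(stacks[[i]], xr[1], xr[2], roi_size)
      } else {
        tf <- if (is.null(transforms[[i]])) identity_transform() else transforms[[i]]
        xt <- apply_transform(tf, matrix(xr, 1))
        xi <- round(xt)
        s <- xt - xi
        roi <- crop_roi_3d(stacks[[i]], as.integer(xi[1]), as.integer(xi[2]),
                           roi_size)
        if (!is.null(roi)) {
          if (tf$mirror_axis != "none") {
            roi <- mirror_stack(roi, tf$mirror_axis)
            if (tf$mirror_axis == "x") s[1] <- -s[1] else s[2] <- -s[2]
          }
          # sample at grid + s so the bead lands where the reference bead is
          roi <- cubic_shift_3d(roi, c(s[1], s[2], 0))
        }
        shifts[i, ] <- s
      }
      if (is.null(roi)) { ok <- FALSE; break }
      chans[[i]] <- roi
    }
    if (!ok) {
      warning("bead at (", xr[1], ", ", xr[2],
              ") out of bounds after transform; skipped")
      next
    }
    out[[length(out) + 1L]] <- list(channels = chans, shifts = shifts,
                                    position = xr)
  }
  out
}

#' Register bead ROIs in 3D and average them into a template
#'
#' Builds an initial template by averaging, registers every bead to it by
#' upscaled 3D cross-correlation (all channels concatenated, so the fixed
#' inter-channel relationship is preserved), rejects beads whose normalized
#' correlation with the template falls below `cutoff`, and re-averages. The
#' second and later rounds register on the central half of the z range.
#'
#' @param rois output of [cut_shifted_rois()].
#' @param n_iter refinement rounds (default 2).
#' @param cutoff normalized-correlation quality cutoff (default 0.9).
#' @param upscale sub-voxel upscaling for the correlation peak.
#' @return list with `template` (list of per-channel 3D arrays), `shifts`
#'   (per-bead 3D shift), `quality`, `accepted` (logical).
#' @export
register_beads_3d <- function(rois, n_iter = 2L, cutoff = 0.9, upscale = 4L) {
  stopifnot(length(rois) >= 1)
  nch <- length(rois[[1]]$channels)
  cat_bead <- function(r) {
    # concatenate channels along z into one 3D array
    do.call(abind3, r$channels)
  }
  beads <- lapply(rois, cat_bead)
  d <- dim(beads[[1]])
  nz1 <- dim(rois[[1]]$channels[[1]])[3]
  template <- Reduce(`+`, beads) / length(beads)
  shifts <- matrix(0, length(beads), 3)
  quality <- rep(NA_real_, length(beads))
  accepted <- rep(TRUE, length(beads))
  zsel <- seq_len(d[3])
  for (it in seq_len(n_iter)) {
    if (it > 1) { # central half of each channel's z range
      q <- nz1 %/% 4
      zc <- (q + 1):(nz1 - q)
      zsel <- as.vector(outer(zc, (seq_len(nch) - 1L) * nz1, `+`))
    }
    tproj <- template[, , zsel, drop = FALSE]
    shifted <- vector("list", length(beads))
    for (b in seq_along(beads)) {
      xc <- xcorr_fft(tproj, beads[[b]][, , zsel, drop = FALSE])
      pk <- refine_peak_subpixel(xc$corr, xc$lags, upscale = upscale,
                                 halfwidth = 2L)
      sh <- c(pk[2], pk[1], pk[3]) # (dx, dy, dz)
      shifts[b, ] <- sh
      # bead content sits at +sh relative to template; move it back
      shifted[[b]] <- cubic_shift_3d(beads[[b]], sh)
      tv <- as.vector(template); bv <- as.vector(shifted[[b]])
      quality[b] <- stats::cor(tv, bv)
      accepted[b] <- is.finite(quality[b]) && quality[b] >= cutoff
    }
    if (!any(accepted))
      stop("calibration failure: all beads rejected at cutoff ", cutoff)
    template <- Reduce(`+`, shifted[accepted]) / sum(accepted)
  }
  tmpl_ch <- lapply(seq_len(nch), function(i)
    template[, , (i - 1L) * nz1 + seq_len(nz1), drop = TRUE])
  list(template = tmpl_ch, shifts = shifts, quality = quality,
       accepted = accepted)
}

abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  nz <- sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], nz))
  at <- 0L
  for (a in arrs) {
    out[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  out
}

# smoothing along z per pixel with a cubic smoothing spline
smooth_stack_z <- function(stack, df_frac = 0.6) {
  d <- dim(stack)
  nz <- d[3]
  if (nz < 6) return(stack)
  df <- max(4, ceiling(df_frac * nz))
  zi <- seq_len(nz)
  m <- matrix(stack, d[1] * d[2], nz)
  sm <- t(apply(m, 1, function(v)
    stats::smooth.spline(zi, v, df = df)$y))
  array(sm, d)
}

#' Build a jointly registered multi-channel spline PSF from bead stacks
#'
#' Orchestrates candidate finding, transform bootstrap (when no transform
#' is supplied: per-channel centroid fits of the bead positions anchor a
#' least-squares transform), transform-aware ROI cutting, 3D registration
#' with quality control, normalization by the sum of the central slice of
#' the reference template, axial smoothing, and per-channel spline fitting.
#'
#' @param stacks list of per-channel 3D bead stacks `[y, x, z]`.
#' @param z_step nm per z slice.
#' @param transforms optional list of [channel_transform()] (reference
#'   first, may be `NULL`); estimated from bead positions when absent.
#' @param roi_size lateral ROI side for the PSF model.
#' @param threshold,rel_threshold candidate detection, see
#'   [find_bead_candidates()].
#' @param n_iter,cutoff registration controls, see [register_beads_3d()].
#' @param smooth_df_frac degrees-of-freedom fraction of the axial
#'   smoothing spline.
#' @param transform_kind family for the bootstrapped transform fit.
#' @return list of class `multichannel_calibration`: `psfs` (per-channel
#'   `cspline_psf`), `transforms`, `normalization`, `quality`, `n_beads`.
#' @export
build_multichannel_psf <- function(stacks, z_step, transforms = NULL,
                                   roi_size = 27, threshold = NULL,
                                   rel_threshold = 0.2, n_iter = 2L,
                                   cutoff = 0.9, smooth_df_frac = 0.6,
                                   transform_kind = "affine") {
  nch <- length(stacks)
  cand <- find_bead_candidates(stacks[[1]], threshold = threshold,
                               rel_threshold = rel_threshold,
                               roi_size = roi_size)
  if (nrow(cand) == 0) stop("no bead candidates found in the reference channel")
  if (nrow(cand) < 3)
    warning("fewer than 3 beads; the averaged PSF model will be noisy")
  if (is.null(transforms)) {
    transforms <- vector("list", nch)
    transforms[[1]] <- identity_transform()
    ref_xy <- refine_positions_centroid(stacks[[1]], cand)
    for (i in seq_len(nch)[-1]) {
      ci <- find_bead_candidates(stacks[[i]], threshold = threshold,
                                 rel_threshold = rel_threshold,
                                 roi_size = roi_size)
      if (nrow(cand) >= 4 && nrow(ci) >= 4) {
        ti_xy <- refine_positions_centroid(stacks[[i]], ci)
        transforms[[i]] <- estimate_transform(
          as.data.frame(ref_xy), as.data.frame(ti_xy),
          rho_schedule = c(3, 1), kind = transform_kind, bin_size = 0.5)
      } else {
        # too few anchors for a full fit: translation-only bootstrap from
        # the z-mean images
        sh <- estimate_shift_xcorr(apply(stacks[[1]], c(1, 2), mean),
                                   apply(stacks[[i]], c(1, 2), mean))
        A <- diag(3); A[1, 3] <- sh[1]; A[2, 3] <- sh[2]
        transforms[[i]] <- channel_transform(A)
      }
    }
  }
  rois <- cut_shifted_rois(stacks, cand, transforms, roi_size = roi_size)
  if (!length(rois)) stop("no usable bead ROIs after transform")
  reg <- register_beads_3d(rois, n_iter = n_iter, cutoff = cutoff)
  norm <- sum(reg$template[[1]][, , (dim(reg$template[[1]])[3] + 1) %/% 2])
  psfs <- lapply(reg$template, function(tm) {
    tm <- tm / norm
    tm <- smooth_stack_z(tm, df_frac = smooth_df_frac)
    fit_cspline(tm, z_step = z_step, normalization = norm)
  })
  out <- list(psfs = psfs, transforms = transforms, normalization = norm,
              quality = reg$quality, accepted = reg$accepted,
              n_beads = sum(reg$accepted), roi_size = roi_size,
              z_step = z_step)
  class(out) <- "multichannel_calibration"
  out
}

# sub-pixel bead positions from background-subtracted centroids of the
# z-mean image (used only to anchor the bootstrap transform)
refine_positions_centroid <- function(stack, cand, halfwin = 5L) {
  mn <- apply(stack, c(1, 2), mean)
  bgl <- stats::median(mn)
  out <- matrix(NA_real_, nrow(cand), 2, dimnames = list(NULL, c("x", "y")))
  for (b in seq_len(nrow(cand))) {
    rows <- (cand[b, 2] - halfwin):(cand[b, 2] + halfwin) + 1L
    cols <- (cand[b, 1] - halfwin):(cand[b, 1] + halfwin) + 1L
    rows <- rows[rows >= 1 & rows <= nrow(mn)]
    cols <- cols[cols >= 1 & cols <= ncol(mn)]
    w <- pmax(mn[rows, cols] - bgl, 0)
    tot <- sum(w)
    out[b, ] <- c(sum(t(w) * (cols - 1L)) / tot, sum(w * (rows - 1L)) / tot)
  }
  out
}

#' Validate a calibration by refitting its own bead stacks
#'
#' Fits every bead at every z slice with the calibrated multi-channel model
#' (all position parameters linked) and compares the fitted z with the
#' slice's nominal z.
#'
#' @param calibration a `multichannel_calibration`.
#' @param stacks the bead stacks (as in [build_multichannel_psf()]).
#' @param z_positions nominal z per slice (nm).
#' @param beads optional candidate positions (found automatically
#'   otherwise).
#' @param fit_roi_size ROI side for the per-slice fits.
#' @param z_fit_range only slices within this range (nm) are fitted.
#' @return data.frame with `bead`, `slice`, `z_true`, `z_fit`, `error`.
#' @export
validate_calibration <- function(calibration, stacks, z_positions,
                                 beads = NULL, fit_roi_size = 15,
                                 z_fit_range = c(-400, 400)) {
  if (is.null(beads))
    beads <- find_bead_candidates(stacks[[1]], roi_size = calibration$roi_size)
  if (length(beads) == 0 || nrow(beads) == 0)
    return(data.frame(bead = integer(0), slice = integer(0),
                      z_true = numeric(0), z_fit = numeric(0),
                      error = numeric(0)))
  nch <- length(stacks)
  link <- link_spec(nch, shared = c("x", "y", "z", "N", "bg"))
  rows <- list()
  rois <- cut_shifted_rois(stacks, beads, calibration$transforms,
                           roi_size = fit_roi_size)
  sel <- which(z_positions >= z_fit_range[1] & z_positions <= z_fit_range[2])
  for (b in seq_along(rois)) {
    for (k in sel) {
      # tiny negatives from the cubic resampling are interpolation ringing
      M <- lapply(rois[[b]]$channels, function(ch) pmax(ch[, , k], 0))
      roi <- multichannel_roi(M, shifts = matrix(0, nch, 2), frame = k)
      fit <- fit_rois_global(list(roi), calibration$psfs, link,
                             ctrl = fit_controls(z_starts = z_positions[k] +
                                                   c(-100, 0, 100)))
      rows[[length(rows) + 1L]] <- data.frame(
        bead = b, slice = k, z_true = z_positions[k], z_fit = fit$z,
        error = fit$z - z_positions[k])
    }
  }
  do.call(rbind, rows)
}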