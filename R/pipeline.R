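# Frame-level processing: difference-of-Gaussians candidate detection,
# cross-channel candidate consolidation, multi-channel ROI extraction with
# residual shifts, and localization post-processing (merging of
# re-activations across consecutive frames, likelihood/precision filters).

#' Detect candidate peaks with a difference-of-Gaussians filter
#'
#' Strict local maxima of `(G_small - G_large) * image` above a threshold;
#' plateau ties break to the smallest (row, col) index.
#'
#' @param frame image matrix (photons).
#' @param sigma_small,sigma_large DoG widths (pixels).
#' @param threshold absolute threshold on the filtered image; `NULL`
#'   estimates it as `k` times a robust noise scale (MAD) of the filtered
#'   image.
#' @param k threshold in noise units when `threshold` is `NULL`.
#' @return integer matrix with columns `x`, `y` (0-based).
#' @export
dog_detect <- function(frame, sigma_small = 1.0, sigma_large = 2.5,
                       threshold = NULL, k = 4) {
  stopifnot(sigma_small < sigma_large)
  dog <- gauss_blur(frame, sigma_small) - gauss_blur(frame, sigma_large)
  if (is.null(threshold))
    threshold <- k * stats::mad(dog)
  stopifnot(threshold > 0)
  pk <- local_maxima(dog, threshold)
  if (nrow(pk) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  cbind(x = pk[, "col"] - 1L, y = pk[, "row"] - 1L)
}

#' Consolidate per-channel detections into reference-channel candidates
#'
#' Maps every channel's peaks back to the reference channel, merges
#' clusters closer than `merge_radius` (single linkage, strict inequality)
#' by averaging, rounds to integer pixels and computes each target
#' channel's residual shift `s = x' - round(x')`.
#'
#' @param peaks list of per-channel peak matrices (columns x, y).
#' @param transforms list of [channel_transform()] (reference first).
#' @param merge_radius merge distance in reference pixels.
#' @param frame frame index stored with the candidates.
#' @return data.frame with `frame`, `x`, `y` (integer reference pixels)
#'   and `sx_ch<i>`, `sy_ch<i>` residual shifts per channel.
#' @export
consolidate_candidates <- function(peaks, transforms, merge_radius = 2,
                                   frame = 1L) {
  stopifnot(merge_radius > 0)
  nch <- length(peaks)
  mapped <- lapply(seq_len(nch), function(i) {
    p <- peaks[[i]]
    if (is.null(p) || nrow(p) == 0) return(NULL)
    if (i == 1L) p else apply_transform(invert_transform(transforms[[i]]), p)
  })
  pts <- do.call(rbind, mapped)
  if (is.null(pts) || nrow(pts) == 0)
    return(empty_candidates(nch))
  # single-linkage clustering within merge_radius
  n <- nrow(pts)
  if (n > 1) {
    cl <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                        h = merge_radius - 1e-9)
  } else cl <- 1L
  ctrs <- t(vapply(split(seq_len(n), cl), function(ix)
    colMeans(pts[ix, , drop = FALSE]), numeric(2)))
  xr <- round(ctrs)
  out <- data.frame(frame = frame, x = as.integer(xr[, 1]),
                    y = as.integer(xr[, 2]))
  for (i in seq_len(nch)) {
    if (i == 1L) { s <- matrix(0, nrow(xr), 2) } else {
      xt <- apply_transform(transforms[[i]], xr)
      s <- xt - round(xt)
      if (transforms[[i]]$mirror_axis == "x") s[, 1] <- -s[, 1]
      if (transforms[[i]]$mirror_axis == "y") s[, 2] <- -s[, 2]
    }
    out[[paste0("sx_ch", i)]] <- s[, 1]
    out[[paste0("sy_ch", i)]] <- s[, 2]
  }
  out
}

empty_candidates <- function(nch) {
  out <- data.frame(frame = integer(0), x = integer(0), y = integer(0))
  for (i in seq_len(nch)) {
    out[[paste0("sx_ch", i)]] <- numeric(0)
    out[[paste0("sy_ch", i)]] <- numeric(0)
  }
  out
}

#' Extract multi-channel ROIs around consolidated candidates
#'
#' Cuts integer crops in every channel (reference at the candidate, target
#' at the rounded transformed position) and stores the residual shifts
#' that the link translates into per-channel position offsets. Mirrored
#' channels are flipped, and their shifts mirrored.
#'
#' @param frames list of per-channel image matrices (one frame).
#' @param candidates data.frame from [consolidate_candidates()].
#' @param transforms list of [channel_transform()].
#' @param roi_size ROI side (odd).
#' @return list of [multichannel_roi()]; out-of-bounds candidates are
#'   dropped (attribute `n_dropped`).
#' @export
extract_rois <- function(frames, candidates, transforms, roi_size = 15) {
  nch <- length(frames)
  half <- (roi_size - 1) %/% 2
  out <- list()
  dropped <- 0L
  for (r in seq_len(nrow(candidates))) {
    xr <- c(candidates$x[r], candidates$y[r])
    M <- vector("list", nch)
    shifts <- matrix(0, nch, 2)
    ok <- TRUE
    for (i in seq_len(nch)) {
      if (i == 1L) { ci <- xr } else {
        xt <- apply_transform(transforms[[i]], matrix(xr, 1))
        ci <- as.integer(round(xt))
        shifts[i, ] <- c(candidates[[paste0("sx_ch", i)]][r],
                         candidates[[paste0("sy_ch", i)]][r])
      }
      img <- frames[[i]]
      rows <- (ci[2] - half):(ci[2] + half) + 1L
      cols <- (ci[1] - half):(ci[1] + half) + 1L
      if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(img) ||
          max(cols) > ncol(img)) { ok <- FALSE; break }
      crop <- img[rows, cols]
      if (i > 1L && transforms[[i]]$mirror_axis == "x")
        crop <- crop[, roi_size:1]
      if (i > 1L && transforms[[i]]$mirror_axis == "y")
        crop <- crop[roi_size:1, ]
      M[[i]] <- crop
    }
    if (!ok) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <- multichannel_roi(M, shifts = shifts,
                                                frame = candidates$frame[r],
                                                origin = xr)
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Merge localizations persisting over consecutive frames
#'
#' Localizations closer than `radius` in consecutive frames (allowing up to
#' `max_gap` empty frames) are merged into one record with photon-weighted
#' mean position, summed photons and the first frame index.
#'
#' @param locs localization data.frame with at least `frame`, `x`, `y`,
#'   `photons`.
#' @param radius merge distance (pixels).
#' @param max_gap maximum frame gap (0 = strictly consecutive).
#' @return merged data.frame; column `n_merged` counts members.
#' @export
merge_consecutive <- function(locs, radius = 0.5, max_gap = 0L) {
  stopifnot(radius > 0, max_gap >= 0)
  if (nrow(locs) < 2) {
    locs$n_merged <- rep(1L, nrow(locs))
    return(locs)
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  n <- nrow(locs)
  group <- seq_len(n)
  # active chains: list of (index of representative row, last frame, x, y)
  active <- data.frame(rep = integer(0), last = integer(0),
                       x = numeric(0), y = numeric(0))
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (r in seq_len(n)) {
    fr <- locs$frame[r]
    active <- active[fr - active$last <= max_gap + 1L, , drop = FALSE]
    if (nrow(active)) {
      d2 <- (active$x - locs$x[r])^2 + (active$y - locs$y[r])^2
      j <- which(d2 < radius^2 & active$last < fr)
      if (length(j)) {
        j <- j[which.min(d2[j])]
        group[r] <- find(active$rep[j])
        active$last[j] <- fr
        active$x[j] <- locs$x[r]; active$y[j] <- locs$y[r]
        next
      }
    }
    active <- rbind(active, data.frame(rep = r, last = fr,
                                       x = locs$x[r], y = locs$y[r]))
  }
  root <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(split(seq_len(n), root), function(ix) {
    sub <- locs[ix, , drop = FALSE]
    w <- sub$photons / sum(sub$photons)
    out <- sub[1, , drop = FALSE]
    out$x <- sum(w * sub$x); out$y <- sum(w * sub$y)
    if (!is.null(sub$z)) out$z <- sum(w * sub$z)
    out$photons <- sum(sub$photons)
    out$frame <- min(sub$frame)
    out$n_merged <- nrow(sub)
    out
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$frame), , drop = FALSE]
}

#' Quantile of the Poisson deviance under a fitted model, by simulation
#'
#' Draws Poisson data around the expected images and evaluates the deviance
#' at the generating parameters, giving a reference distribution for the
#' likelihood filter.
#'
#' @param mu_list per-channel expected images.
#' @param q quantile (e.g. 0.999).
#' @param nsim simulation draws.
#' @return the deviance quantile.
#' @export
chi2_null_quantile <- function(mu_list, q = 0.999, nsim = 200) {
  sims <- vapply(seq_len(nsim), function(s) {
    sum(vapply(mu_list, function(mu) {
      M <- matrix(stats::rpois(length(mu), mu), nrow(mu))
      mle_objective(M, pmax(mu, 1e-6))
    }, numeric(1)))
  }, numeric(1))
  stats::quantile(sims, q, names = FALSE)
}

#' Filter localizations on fit quality and precision
#'
#' Removes rows whose Poisson deviance exceeds the simulated quantile of
#' its expected distribution (binned by photon count), or whose lateral
#' precision `sqrt(crlb_x + crlb_y)` exceeds `precision_cut`.
#'
#' @param locs localization data.frame with `chi2`, `photons`, `bg` and
#'   `crlb_x`, `crlb_y` columns.
#' @param psfs per-channel PSF models used for the fits (needed for the
#'   deviance reference; omit to skip the deviance filter).
#' @param link the [link_spec()] used for the fits.
#' @param roi_size ROI side used for the fits.
#' @param chi2_quantile deviance quantile cut (e.g. 0.999; `NULL` or `Inf`
#'   disables).
#' @param precision_cut lateral precision cut in pixels (`Inf` disables).
#' @param n_bins photon bins for the deviance reference.
#' @param nsim simulation draws per bin.
#' @return filtered data.frame; attribute `n_removed`.
#' @export
filter_locs <- function(locs, psfs = NULL, link = NULL, roi_size = 15,
                        chi2_quantile = NULL, precision_cut = Inf,
                        n_bins = 4, nsim = 200) {
  keep <- rep(TRUE, nrow(locs))
  if (!is.null(chi2_quantile) && is.finite(chi2_quantile) &&
      !is.null(psfs) && nrow(locs) > 0) {
    psfs <- as_psf_set(psfs, if (is.null(link)) 2L else link$n_channels)
    bins <- if (n_bins > 1 && nrow(locs) > 1)
      cut(rank(locs$photons, ties.method = "first"), n_bins, labels = FALSE)
    else rep(1L, nrow(locs))
    for (b in unique(bins)) {
      ix <- which(bins == b)
      med <- ix[which.min(abs(locs$photons[ix] -
                                stats::median(locs$photons[ix])))]
      nch <- length(psfs)
      ctr <- (roi_size - 1) / 2
      mu_list <- lapply(seq_len(nch), function(i) {
        Ni <- locs[[paste0("photons_ch", i)]]
        Ni <- if (is.null(Ni)) locs$photons[med] / nch else Ni[med]
        evaluate_channel(psfs[[i]],
                         list(x = ctr, y = ctr,
                              z = if (is.null(locs$z)) 0 else locs$z[med],
                              N = Ni, bg = locs$bg[med]),
                         roi_size, channel = i)
      })
      cut_val <- chi2_null_quantile(mu_list, q = chi2_quantile, nsim = nsim)
      keep[ix] <- keep[ix] & locs$chi2[ix] <= cut_val
    }
  }
  if (is.finite(precision_cut)) {
    prec <- sqrt(locs$crlb_x + locs$crlb_y)
    keep <- keep & prec <= precision_cut & is.finite(prec)
  }
  out <- locs[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
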