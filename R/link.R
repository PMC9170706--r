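# Parameter linking: which fit parameters are shared (global) across
# channels and which are per-channel (local). A shared parameter theta_p
# maps into channel i as theta_pi = S_pi * theta_p + dtheta_pi; the
# translation for x and y is the per-ROI residual shift s between the
# transformed and the rounded ROI origin, and a mirrored channel is
# expressed through S_xi = -1.

#' Declare shared and local fit parameters
#'
#' @param n_channels number of detection channels.
#' @param shared character vector of parameter names fitted as one global
#'   value (any of `params`).
#' @param params ordered parameter names of the channel model; use
#'   `c("x","y","z","N","bg","phi")` for interferometric fits.
#' @param S optional named list of per-channel scale vectors (length
#'   `n_channels`), e.g. `list(N = c(0.5, 0.5))` for a 1:1 photon split or
#'   `list(x = c(1, -1))` for a mirrored channel. Defaults to 1. The
#'   reference channel (first) keeps `S = 1`, `dtheta = 0` for x and y.
#' @param delta optional named list of per-channel translation vectors;
#'   the x/y rows are overridden per ROI by the stored residual shifts.
#' @return object of class `link_spec`.
#' @export
link_spec <- function(n_channels, shared = c("x", "y", "z"),
                      params = c("x", "y", "z", "N", "bg"),
                      S = NULL, delta = NULL) {
  stopifnot(n_channels >= 1, all(shared %in% params))
  np <- length(params)
  Sm <- matrix(1, np, n_channels, dimnames = list(params, NULL))
  Dm <- matrix(0, np, n_channels, dimnames = list(params, NULL))
  for (nm in names(S)) Sm[nm, ] <- S[[nm]]
  for (nm in names(delta)) Dm[nm, ] <- delta[[nm]]
  is_shared <- stats::setNames(params %in% shared, params)
  shared_names <- params[is_shared]
  local_names <- params[!is_shared]
  gnames <- c(shared_names,
              unlist(lapply(seq_len(n_channels), function(i)
                if (length(local_names)) paste0(local_names, "_ch", i) else character(0))))
  gidx <- matrix(0L, np, n_channels, dimnames = list(params, NULL))
  ns <- length(shared_names); nl <- length(local_names)
  for (i in seq_len(n_channels)) {
    gidx[is_shared, i] <- match(params[is_shared], shared_names)
    if (nl) gidx[!is_shared, i] <- ns + (i - 1L) * nl + seq_len(nl)
  }
  scale <- Sm
  scale[!is_shared, ] <- 1
  local_gidx <- if (nl) (ns + 1L):(ns + nl * n_channels) else integer(0)
  obj <- list(params = params, n_channels = n_channels, shared = is_shared,
              S = Sm, delta = Dm, gnames = gnames, gidx = gidx, scale = scale,
              n_global = length(gnames), n_shared = ns, local_gidx = local_gidx)
  class(obj) <- "link_spec"
  obj
}

# Per-channel parameter matrix (params x channels) from the global vector.
# shifts: n_channels x 2 matrix of residual ROI shifts (dx, dy) or NULL.
link_channel_params <- function(link, theta, shifts = NULL) {
  delta <- link$delta
  if (!is.null(shifts)) {
    delta["x", ] <- delta["x", ] + shifts[, 1]
    delta["y", ] <- delta["y", ] + shifts[, 2]
  }
  th <- matrix(theta[link$gidx], length(link$params), link$n_channels,
               dimnames = list(link$params, NULL))
  sh <- link$shared
  th[sh, ] <- link$S[sh, , drop = FALSE] * th[sh, , drop = FALSE] +
    delta[sh, , drop = FALSE]
  th
}

#' Photon ratio set for fixed-ratio (dye hypothesis) fitting
#'
#' Each dye has a calibrated photon ratio `r = I2 / I1` between the dark and
#' the bright spectral channel; the implied channel scales for a shared total
#' photon count are `S1 = 1/(1+r)` and `S2 = r/(1+r)`.
#'
#' @param ratios numeric vector of `I2/I1` ratios, one per dye.
#' @param labels dye names; defaults to `dye1..dyeK`.
#' @return data.frame with columns `label`, `r`, `S1`, `S2`.
#' @export
dye_ratio_set <- function(ratios, labels = NULL) {
  stopifnot(all(ratios >= 0))
  if (is.null(labels)) labels <- paste0("dye", seq_along(ratios))
  data.frame(label = labels, r = ratios,
             S1 = 1 / (1 + ratios), S2 = ratios / (1 + ratios),
             stringsAsFactors = FALSE)
}

#' Container for one multi-channel candidate ROI
#'
#' @param M list of per-channel pixel matrices (photons).
#' @param shifts `n_channels x 2` matrix of residual sub-pixel shifts
#'   `(dx, dy)`; the reference channel row is zero.
#' @param frame frame index.
#' @param origin integer ROI origin `(x, y)` in the reference channel.
#' @return object of class `multichannel_roi`.
#' @export
multichannel_roi <- function(M, shifts = NULL, frame = 1L, origin = c(0L, 0L)) {
  stopifnot(is.list(M), length(M) >= 1)
  dims <- vapply(M, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all channel ROIs must have the same shape")
  if (any(vapply(M, function(m) any(m < 0), logical(1)))) {
    warning("negative pixel values clipped to 0")
    M <- lapply(M, function(m) pmax(m, 0))
  }
  if (is.null(shifts)) shifts <- matrix(0, length(M), 2)
  obj <- list(M = M, shifts = shifts, frame = frame, origin = origin,
              roi_size = dims[1, 1])
  class(obj) <- "multichannel_roi"
  obj
}

# Normalize a PSF argument into a per-channel list. A single interferometric
# model expands to one entry per phase channel; a single other model is
# reused for every channel.
as_psf_set <- function(psfs, n_channels) {
  if (inherits(psfs, "psf_model")) {
    if (inherits(psfs, "fourpi_psf")) n_channels <- psf_n_channels(psfs)
    psfs <- rep(list(psfs), n_channels)
  }
  stopifnot(length(psfs) == n_channels)
  psfs
}
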