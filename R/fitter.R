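# Global maximum-likelihood fitter: Poisson deviance objective, score and
# Fisher-style Hessian assembly over linked channels, Levenberg-Marquardt
# minimization with damped diagonal, CRLB computation, CRLB-weighted
# averaging of independent per-channel fits, and fixed-photon-ratio
# hypothesis fitting.
#
# Sign convention: the assembled score J is the derivative of the Poisson
# log-likelihood scaled as J = -(1/2) * d(chi2_mle)/d(theta); the L-M update
# solves (H + lambda * diag(H)) dtheta = J and steps theta <- theta + dtheta,
# which decreases chi2_mle for small enough damping.

#' Poisson deviance of measured vs expected pixels
#'
#' `chi2_mle = 2 * sum((mu - M) - M * log(mu / M))`, where the log term is
#' restricted to pixels with `M > 0`. Zero when `mu == M` elementwise, and
#' asymptotically chi-square distributed for a correct model.
#'
#' @param M measured photons (vector/matrix).
#' @param mu expected photons, strictly positive, same shape as `M`.
#' @return non-negative scalar.
#' @export
mle_objective <- function(M, mu) {
  if (!identical(dim(M), dim(mu)) || length(M) != length(mu))
    stop("M and mu must have identical shapes")
  pos <- M > 0
  2 * (sum(mu - M) - sum(M[pos] * log(mu[pos] / M[pos])))
}

#' Levenberg-Marquardt fit controls
#'
#' @param lambda0 initial damping.
#' @param lambda_up,lambda_down multiplicative damping schedule on
#'   rejection/acceptance.
#' @param lambda_min,lambda_max damping floor and cap.
#' @param tol relative chi2 decrease below which (on two consecutive
#'   accepted steps) the fit is declared converged.
#' @param max_iter maximum accepted iterations.
#' @param z_starts multi-start z values (nm); `NULL` selects a model-based
#'   initializer (moment inversion for Gaussian models, `c(-300, 0, 300)`
#'   for spline models).
#' @param full_hessian keep the within-channel local-local cross terms of
#'   the Hessian instead of the default diagonal-only local block.
#' @param mu_floor clamp on expected photons per pixel.
#' @export
fit_controls <- function(lambda0 = 0.1, lambda_up = 10, lambda_down = 10,
                         lambda_min = 1e-7, lambda_max = 1e7, tol = 1e-6,
                         max_iter = 100L, z_starts = NULL,
                         full_hessian = FALSE, mu_floor = 1e-6) {
  list(lambda0 = lambda0, lambda_up = lambda_up, lambda_down = lambda_down,
       lambda_min = lambda_min, lambda_max = lambda_max, tol = tol,
       max_iter = max_iter, z_starts = z_starts,
       full_hessian = full_hessian, mu_floor = mu_floor)
}

# Evaluate chi2 only (cheap path used when testing a proposed step).
chi2_at <- function(Mlist, psfs, link, theta, shifts, roi_size, mu_floor) {
  th <- link_channel_params(link, theta, shifts)
  chi2 <- 0
  for (i in seq_along(Mlist)) {
    p <- as.list(th[, i])
    mu <- evaluate_channel(psfs[[i]], p, roi_size, channel = i,
                           mu_floor = mu_floor)
    chi2 <- chi2 + mle_objective(as.vector(Mlist[[i]]), as.vector(mu))
  }
  chi2
}

#' Assemble the global score vector and Hessian for one multi-channel ROI
#'
#' Shared-parameter rows accumulate channel contributions weighted by their
#' scales S; local parameters of different channels never mix. By default
#' the local-local block of the Hessian keeps only its diagonal (the form
#' the fitter iterates with); `full_hessian = TRUE` retains the
#' within-channel local cross terms.
#'
#' @param roi a [multichannel_roi()].
#' @param psfs per-channel PSF models (or a single model, recycled).
#' @param theta global parameter vector (layout: shared, then per-channel
#'   locals).
#' @param link a [link_spec()].
#' @param full_hessian see above.
#' @param mu_floor clamp on expected photons.
#' @return list with `J` (score), `H` (Hessian approximation), `chi2`.
#' @export
assemble_jacobian_hessian <- function(roi, psfs, theta, link,
                                      full_hessian = FALSE, mu_floor = 1e-6) {
  psfs <- as_psf_set(psfs, link$n_channels)
  out <- assemble_jh(roi$M, psfs, link, theta, roi$shifts, roi$roi_size,
                     full_hessian = full_hessian, mu_floor = mu_floor)
  out
}

assemble_jh <- function(Mlist, psfs, link, theta, shifts, roi_size,
                        full_hessian = FALSE, mu_floor = 1e-6,
                        fisher = FALSE) {
  ng <- link$n_global
  J <- numeric(ng)
  H <- matrix(0, ng, ng)
  Fi <- if (fisher) matrix(0, ng, ng) else NULL
  th <- link_channel_params(link, theta, shifts)
  chi2 <- 0
  for (i in seq_along(Mlist)) {
    p <- as.list(th[, i])
    ed <- evaluate_derivatives(psfs[[i]], p, roi_size, channel = i,
                               mu_floor = mu_floor)
    mu <- ed$mu
    if (!all(is.finite(mu)) || !all(is.finite(ed$D)))
      stop("non-finite model value or derivative in channel ", i)
    M <- as.vector(Mlist[[i]])
    pos <- M > 0
    chi2 <- chi2 + 2 * (sum(mu - M) -
                          sum(M[pos] * log(mu[pos] / M[pos])))
    w1 <- (M - mu) / mu
    w2 <- M / mu^2
    gi <- link$gidx[, i]
    sc <- link$scale[, i]
    jc <- as.vector(crossprod(ed$D, w1)) * sc
    Hc <- crossprod(ed$D, ed$D * w2) * tcrossprod(sc)
    J[gi] <- J[gi] + jc
    H[gi, gi] <- H[gi, gi] + Hc
    if (fisher) {
      Fc <- crossprod(ed$D, ed$D / mu) * tcrossprod(sc)
      Fi[gi, gi] <- Fi[gi, gi] + Fc
    }
  }
  if (!full_hessian && length(link$local_gidx) > 1) {
    lg <- link$local_gidx
    sub <- H[lg, lg]
    H[lg, lg] <- diag(diag(sub), length(lg))
  }
  names(J) <- link$gnames
  dimnames(H) <- list(link$gnames, link$gnames)
  list(J = J, H = H, chi2 = chi2, fisher = Fi)
}

#' One damped Levenberg-Marquardt update
#'
#' Solves `(H + lambda * diag(H)) dtheta = J`.
#'
#' @param J score vector.
#' @param H Hessian approximation (symmetric).
#' @param lambda damping factor, >= 0.
#' @return the update `dtheta`.
#' @export
lm_step <- function(J, H, lambda) {
  d <- diag(H)
  ridge <- 1e-12 * max(d, 1e-300)
  A <- H + diag(lambda * d + ridge, nrow(H))
  solve(A, J)
}

# Parameter bounds in global coordinates.
link_bounds <- function(link, psfs, roi_size) {
  zr <- range(vapply(psfs, function(p) psf_z_range(p), numeric(2)))
  zr <- c(max(vapply(psfs, function(p) psf_z_range(p)[1], numeric(1))),
          min(vapply(psfs, function(p) psf_z_range(p)[2], numeric(1))))
  lower_of <- function(nm) switch(sub("_ch[0-9]+$", "", nm),
    x = -1, y = -1, z = zr[1], N = 1e-3, bg = 0, phi = -Inf)
  upper_of <- function(nm) switch(sub("_ch[0-9]+$", "", nm),
    x = roi_size, y = roi_size, z = zr[2], N = Inf, bg = Inf, phi = Inf)
  list(lower = vapply(link$gnames, lower_of, numeric(1)),
       upper = vapply(link$gnames, upper_of, numeric(1)))
}

clamp_theta <- function(theta, bounds) {
  pmin(pmax(theta, bounds$lower), bounds$upper)
}

# Single L-M minimization from one start. Returns theta, chi2, iterations,
# converged flag.
fit_one_start <- function(Mlist, psfs, link, shifts, roi_size, theta0, ctrl,
                          bounds) {
  theta <- clamp_theta(theta0, bounds)
  lambda <- ctrl$lambda0
  jh <- tryCatch(
    assemble_jh(Mlist, psfs, link, theta, shifts, roi_size,
                full_hessian = ctrl$full_hessian, mu_floor = ctrl$mu_floor),
    error = function(e) NULL)
  if (is.null(jh))
    return(list(theta = theta, chi2 = Inf, iterations = 0L,
                converged = FALSE))
  chi2 <- jh$chi2
  iter <- 0L
  converged <- FALSE
  small_steps <- 0L
  while (iter < ctrl$max_iter) {
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(lm_step(jh$J, jh$H, lambda), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        cand <- clamp_theta(theta + step, bounds)
        # evaluating the candidate's score/Hessian here lets an accepted
        # step reuse them for the next iteration
        jh_cand <- tryCatch(
          assemble_jh(Mlist, psfs, link, cand, shifts, roi_size,
                      full_hessian = ctrl$full_hessian,
                      mu_floor = ctrl$mu_floor),
          error = function(e) NULL)
        if (!is.null(jh_cand) && is.finite(jh_cand$chi2) &&
            jh_cand$chi2 <= chi2) {
          rel <- (chi2 - jh_cand$chi2) / max(abs(chi2), 1)
          theta <- cand
          chi2 <- jh_cand$chi2
          jh <- jh_cand
          lambda <- max(lambda / ctrl$lambda_down, ctrl$lambda_min)
          accepted <- TRUE
          iter <- iter + 1L
          small_steps <- if (rel < ctrl$tol) small_steps + 1L else 0L
          if (small_steps >= 2L) converged <- TRUE
        }
      }
      if (!accepted) {
        lambda <- lambda * ctrl$lambda_up
        if (lambda > ctrl$lambda_max) break
      }
    }
    if (!accepted || converged) break
  }
  list(theta = theta, chi2 = chi2, iterations = iter, converged = converged)
}

# ---- initialization -------------------------------------------------------

# Model width curves sigma_x(z), sigma_y(z) from rendered centered model
# images, on a shared z grid. Used by the moment-based z initializer; the
# four phase channels of an interferometric model are represented by their
# envelope (summing the quadrature channels cancels the fringe).
# Second moments in a window around the centroid. The window suppresses the
# positive halo that background-noise clipping adds at large radii; the same
# estimator is applied to model images and data so the matching stays
# consistent.
windowed_moments <- function(w, halfwin = 5L) {
  n <- nrow(w)
  u <- 0:(n - 1)
  tot <- sum(w)
  if (tot <= 0) return(c(NA, NA, NA, NA))
  cx <- sum(t(w) * u) / tot
  cy <- sum(w * u) / tot
  rows <- which(abs(u - cy) <= halfwin)
  cols <- which(abs(u - cx) <= halfwin)
  ww <- w[rows, cols, drop = FALSE]
  tot <- sum(ww)
  if (tot <= 0) return(c(NA, NA, NA, NA))
  ux <- u[cols]; uy <- u[rows]
  cx <- sum(t(ww) * ux) / tot
  cy <- sum(ww * uy) / tot
  c(sqrt(sum(t(ww) * (ux - cx)^2) / tot),
    sqrt(sum(ww * (uy - cy)^2) / tot), cx, cy)
}

psf_width_tables <- function(psfs, roi_size, z_step = 25) {
  base <- lapply(psfs, function(p) if (inherits(p, "fourpi_psf")) p$envelope else p)
  zr <- c(max(vapply(base, function(p) psf_z_range(p)[1], numeric(1))),
          min(vapply(base, function(p) psf_z_range(p)[2], numeric(1))))
  zg <- seq(zr[1] + 1e-9, zr[2] - 1e-9, by = z_step)
  ctr <- (roi_size - 1) / 2
  tabs <- lapply(base, function(p) {
    sx <- numeric(length(zg)); sy <- numeric(length(zg))
    for (k in seq_along(zg)) {
      w <- matrix(psf_eval_raw(p, ctr, ctr, zg[k], roi_size)$val,
                  roi_size, roi_size)
      m <- windowed_moments(w)
      sx[k] <- m[1]; sy[k] <- m[2]
    }
    list(sx = sx, sy = sy)
  })
  list(z = zg, tables = tabs)
}

# Moment-based z initializer: pick the z whose model width curves best match
# the observed background-subtracted second moments. Width-encoded axial
# information is often bifold-ambiguous (defocus branches), so both the best
# and the best well-separated local minimum of the matching cost are
# returned; the L-M loop resolves the branch by likelihood.
z_init_moments <- function(Mlist, psfs, bg0, roi_size, wt = NULL) {
  if (inherits(psfs[[1]], "fourpi_psf")) {
    Mlist <- list(Reduce(`+`, Mlist))
    bg0 <- sum(bg0)
    psfs <- psfs[1]
  }
  if (is.null(wt)) wt <- psf_width_tables(psfs, roi_size)
  obs <- lapply(seq_along(Mlist), function(i) {
    windowed_moments(pmax(Mlist[[i]] - bg0[i], 0))[1:2]
  })
  zg <- wt$z
  cost <- numeric(length(zg))
  for (i in seq_along(Mlist)) {
    if (any(is.na(obs[[i]]))) next
    cost <- cost + (wt$tables[[i]]$sx - obs[[i]][1])^2 +
      (wt$tables[[i]]$sy - obs[[i]][2])^2
  }
  best <- zg[which.min(cost)]
  n <- length(cost)
  locmin <- which(cost <= c(Inf, cost[-n]) & cost <= c(cost[-1], Inf))
  locmin <- locmin[abs(zg[locmin] - best) > 150]
  if (length(locmin)) c(best, zg[locmin[which.min(cost[locmin])]]) else best
}

#' Starting values for a multi-channel ROI fit
#'
#' Background from the median ROI border pixel, photons from the
#' background-subtracted sum, position from the photon-weighted centroid
#' mapped back through the residual shifts, z from moment inversion
#' (Gaussian-width models) or a multi-start set, and the interference phase
#' from the quadrature of the four channel photon sums.
#'
#' @param roi a [multichannel_roi()].
#' @param psfs per-channel PSF models.
#' @param link a [link_spec()].
#' @param width_tables optional precomputed [psf_width_tables()] result.
#' @return named global parameter vector (attribute `z_starts` holds the
#'   candidate axial starting values).
#' @export
initial_estimates <- function(roi, psfs, link, width_tables = NULL) {
  psfs <- as_psf_set(psfs, link$n_channels)
  Mlist <- roi$M
  R <- roi$roi_size
  if (all(vapply(Mlist, function(m) all(m == 0), logical(1))))
    stop("degenerate input: all-zero ROI")
  border <- c(1L, R)
  bg0 <- vapply(Mlist, function(m)
    stats::median(c(m[border, ], m[, border])), numeric(1))
  N0 <- vapply(seq_along(Mlist), function(i)
    max(sum(Mlist[[i]]) - bg0[i] * R * R, 1), numeric(1))
  u <- 0:(R - 1)
  cxy <- vapply(seq_along(Mlist), function(i) {
    w <- pmax(Mlist[[i]] - bg0[i], 0)
    tot <- sum(w)
    if (tot <= 0) return(c((R - 1) / 2, (R - 1) / 2))
    c(sum(t(w) * u) / tot, sum(w * u) / tot)
  }, numeric(2))
  # map each channel's centroid back to reference coordinates
  wN <- N0 / sum(N0)
  Sx <- link$scale["x", ]; Sy <- link$scale["y", ]
  x0 <- sum(wN * (cxy[1, ] - roi$shifts[, 1] - link$delta["x", ]) / Sx)
  y0 <- sum(wN * (cxy[2, ] - roi$shifts[, 2] - link$delta["y", ]) / Sy)
  z_cand <- z_init_moments(Mlist, psfs, bg0, R, wt = width_tables)
  z0 <- if (is.null(z_cand)) 0 else z_cand[1]
  theta <- numeric(link$n_global)
  names(theta) <- link$gnames
  set_par <- function(theta, nm, per_channel, combine_shared) {
    if (link$shared[nm]) {
      theta[nm] <- combine_shared
    } else {
      theta[paste0(nm, "_ch", seq_len(link$n_channels))] <- per_channel
    }
    theta
  }
  theta <- set_par(theta, "x", cxy[1, ], x0)
  theta <- set_par(theta, "y", cxy[2, ], y0)
  theta <- set_par(theta, "z", rep(z0, link$n_channels), z0)
  theta <- set_par(theta, "N", N0, sum(N0) / sum(link$S["N", ]))
  theta <- set_par(theta, "bg", bg0, mean(bg0))
  if ("phi" %in% link$params) {
    P <- N0
    # quadrature estimate of the total fringe phase psi = 2 k_z z + phi
    psi0 <- if (length(P) == 4) {
      off <- if (inherits(psfs[[1]], "fourpi_psf")) psfs[[1]]$offsets else
        c(0, pi / 2, pi, 3 * pi / 2)
      atan2(-sum(P * sin(off)), sum(P * cos(off)))
    } else 0
    phi0 <- psi0
    # remove the deterministic 2 k_z z part so phi starts near the offset
    if (inherits(psfs[[1]], "fourpi_psf"))
      phi0 <- wrap_phase(psi0 - 2 * psfs[[1]]$k_z * z0)
    theta <- set_par(theta, "phi", rep(phi0, link$n_channels), phi0)
    attr(theta, "psi_quad") <- psi0
  }
  attr(theta, "z_starts") <- z_cand
  theta
}

default_z_starts <- function(psfs, z0, ctrl, candidates = NULL) {
  if (!is.null(ctrl$z_starts)) return(ctrl$z_starts)
  if (!is.null(candidates)) return(candidates)
  zr <- c(max(vapply(psfs, function(p) psf_z_range(p)[1], numeric(1))),
          min(vapply(psfs, function(p) psf_z_range(p)[2], numeric(1))))
  pmin(pmax(c(-300, 0, 300), zr[1] + 1e-6), zr[2] - 1e-6)
}

#' Jointly fit multi-channel ROIs by global maximum likelihood
#'
#' Runs the damped Levenberg-Marquardt loop per ROI with the declared
#' parameter linking, multi-starting over z when the model requires it,
#' and attaches the per-parameter CRLB evaluated at the optimum.
#'
#' @param rois list of [multichannel_roi()] objects.
#' @param psfs per-channel PSF models (single model recycled; a
#'   `fourpi_psf` expands to its phase channels).
#' @param link a [link_spec()].
#' @param theta0 optional matrix (one row per ROI) or vector of starting
#'   values; default uses [initial_estimates()].
#' @param ctrl a [fit_controls()] list.
#' @return data.frame, one row per ROI: global parameter estimates, their
#'   `crlb_*` variances, per-channel photons, `chi2`, `iterations`,
#'   `converged`, `frame`.
#' @export
fit_rois_global <- function(rois, psfs, link, theta0 = NULL,
                            ctrl = fit_controls()) {
  stopifnot(length(rois) >= 1)
  psfs <- as_psf_set(psfs, link$n_channels)
  R <- rois[[1]]$roi_size
  bounds <- link_bounds(link, psfs, R)
  ng <- link$n_global
  n <- length(rois)
  est <- matrix(NA_real_, n, ng, dimnames = list(NULL, link$gnames))
  crlb <- matrix(NA_real_, n, ng,
                 dimnames = list(NULL, paste0("crlb_", link$gnames)))
  chi2 <- numeric(n); iters <- integer(n); conv <- logical(n)
  photons <- matrix(NA_real_, n, link$n_channels,
                    dimnames = list(NULL, paste0("photons_ch",
                                                 seq_len(link$n_channels))))
  frames <- integer(n)
  wt <- psf_width_tables(psfs, R)
  for (r in seq_len(n)) {
    roi <- rois[[r]]
    t0 <- if (is.null(theta0)) initial_estimates(roi, psfs, link,
                                                 width_tables = wt)
          else if (is.matrix(theta0)) theta0[r, ] else theta0
    zname <- if (link$shared["z"]) "z" else "z_ch1"
    zstarts <- default_z_starts(psfs, t0[[zname]], ctrl,
                                candidates = attr(t0, "z_starts"))
    if (inherits(psfs[[1]], "fourpi_psf") && is.null(ctrl$z_starts)) {
      # the envelope start can sit on a neighbouring fringe; test both
      # half-period neighbours (the phase is re-synced per start below)
      halfp <- pi / (2 * psfs[[1]]$k_z)
      zr <- psf_z_range(psfs[[1]])
      zstarts <- unique(pmin(pmax(c(zstarts, zstarts[1] + halfp,
                                    zstarts[1] - halfp),
                                  zr[1] + 1e-6), zr[2] - 1e-6))
    }
    # multi-start: when several axial starts exist, explore each with a
    # short iteration budget, then converge only the best basin
    explore <- ctrl
    if (length(zstarts) > 1L)
      explore$max_iter <- min(ctrl$max_iter, 15L)
    best <- NULL
    for (zs in zstarts) {
      ti <- t0
      if (link$shared["z"]) ti["z"] <- zs
      else ti[paste0("z_ch", seq_len(link$n_channels))] <- zs
      # keep the fringe phase consistent with each axial start
      if ("phi" %in% link$params && inherits(psfs[[1]], "fourpi_psf") &&
          !is.null(attr(t0, "psi_quad"))) {
        phi_s <- wrap_phase(attr(t0, "psi_quad") - 2 * psfs[[1]]$k_z * zs)
        if (link$shared["phi"]) ti["phi"] <- phi_s
        else ti[paste0("phi_ch", seq_len(link$n_channels))] <- phi_s
      }
      fit <- fit_one_start(roi$M, psfs, link, roi$shifts, R, ti, explore,
                           bounds)
      fit$zstart <- zs
      if (is.null(best) || fit$chi2 < best$chi2 - 1e-9 ||
          (abs(fit$chi2 - best$chi2) <= 1e-9 &&
           abs(fit$theta[[zname]]) < abs(best$theta[[zname]])))
        best <- fit
    }
    if (length(zstarts) > 1L && !best$converged) {
      more <- fit_one_start(roi$M, psfs, link, roi$shifts, R, best$theta,
                            ctrl, bounds)
      more$iterations <- more$iterations + best$iterations
      best <- more
    }
    est[r, ] <- best$theta
    chi2[r] <- best$chi2
    iters[r] <- best$iterations
    conv[r] <- best$converged
    frames[r] <- roi$frame
    cb <- tryCatch(
      compute_crlb(psfs, best$theta, link, shifts = roi$shifts, roi_size = R,
                   mu_floor = ctrl$mu_floor),
      error = function(e) rep(NA_real_, ng))
    crlb[r, ] <- cb
    thch <- link_channel_params(link, best$theta, roi$shifts)
    photons[r, ] <- thch["N", ]
  }
  out <- data.frame(est, crlb, photons, chi2 = chi2, iterations = iters,
                    converged = conv, frame = frames, check.names = FALSE)
  out
}

#' Cramer-Rao lower bounds for a linked multi-channel fit
#'
#' Fisher information `F_mn = sum_i sum_k (dmu/dtheta_m)(dmu/dtheta_n)/mu`
#' accumulated with the same shared/local layout and channel scales as the
#' fitter; the CRLB is the diagonal of its inverse. Cross-channel
#' local-local entries are exactly zero; within-channel local cross terms
#' are kept, as the bound is a property of the model, not of the optimizer.
#'
#' @param psfs per-channel PSF models.
#' @param theta global parameter vector (e.g. truth, or an estimate).
#' @param link a [link_spec()].
#' @param shifts residual-shift matrix (default zero).
#' @param roi_size ROI side length.
#' @param mu_floor clamp on expected photons.
#' @return named vector of per-parameter variance lower bounds.
#' @export
compute_crlb <- function(psfs, theta, link, shifts = NULL, roi_size,
                         mu_floor = 1e-6) {
  psfs <- as_psf_set(psfs, link$n_channels)
  if (is.null(shifts)) shifts <- matrix(0, link$n_channels, 2)
  # dummy measured values: the Fisher path only uses mu
  Mlist <- rep(list(matrix(0, roi_size, roi_size)), link$n_channels)
  jh <- assemble_jh(Mlist, psfs, link, theta, shifts, roi_size,
                    full_hessian = TRUE, mu_floor = mu_floor, fisher = TRUE)
  Fi <- jh$fisher
  inv <- tryCatch(solve(Fi), error = function(e) {
    worst <- link$gnames[which.min(abs(diag(Fi)))]
    stop("Fisher matrix is singular; parameter '", worst,
         "' appears unidentifiable", call. = FALSE)
  })
  stats::setNames(diag(inv), paste0("crlb_", link$gnames))
}

#' Inverse-variance (CRLB-weighted) combination of per-channel estimates
#'
#' @param estimates numeric vector (or matrix, rows combined independently)
#'   of per-channel estimates.
#' @param variances matching CRLB variances, positive (Inf allowed).
#' @return list with `estimate` and `variance`.
#' @export
crlb_weighted_average <- function(estimates, variances) {
  if (is.null(dim(estimates))) {
    estimates <- matrix(estimates, 1)
    variances <- matrix(variances, 1)
  }
  if (any(variances <= 0, na.rm = TRUE)) stop("variances must be positive")
  w <- 1 / variances
  wt <- rowSums(w)
  if (any(wt == 0)) stop("all variances are infinite: average undefined")
  list(estimate = rowSums(estimates * w) / wt, variance = 1 / wt)
}

#' Fixed-photon-ratio fitting with maximum-likelihood dye selection
#'
#' Fits every ROI once per dye hypothesis with the total photon count shared
#' and the per-channel scales fixed from the dye's calibrated ratio, then
#' selects the hypothesis with the smallest Poisson deviance. Ties break to
#' the first (lowest-index) dye.
#'
#' @param rois list of [multichannel_roi()] objects (two channels).
#' @param psfs per-channel PSF models.
#' @param ratios a [dye_ratio_set()] (or numeric vector of I2/I1 ratios).
#' @param link_base a [link_spec()] for the non-photon parameters; its `N`
#'   entry is forced shared with the hypothesis scales.
#' @param ctrl a [fit_controls()] list.
#' @return list with `dye` (winning label per ROI), `chi2` (ROI x dye
#'   matrix), `fits` (data.frame of the winning fit per ROI), `ratios`.
#' @export
fit_fixed_ratio <- function(rois, psfs, ratios, link_base = NULL,
                            ctrl = fit_controls()) {
  if (!is.data.frame(ratios)) ratios <- dye_ratio_set(ratios)
  if (nrow(ratios) < 1) stop("ratio set must be non-empty")
  nch <- 2L
  if (is.null(link_base))
    link_base <- link_spec(nch, shared = c("x", "y", "z", "N", "bg"))
  shared <- union(names(link_base$shared)[link_base$shared], "N")
  chi2 <- matrix(NA_real_, length(rois), nrow(ratios),
                 dimnames = list(NULL, ratios$label))
  fits <- vector("list", nrow(ratios))
  for (d in seq_len(nrow(ratios))) {
    Slist <- list(N = c(ratios$S1[d], ratios$S2[d]))
    link <- link_spec(nch, shared = shared, params = link_base$params,
                      S = Slist)
    fits[[d]] <- fit_rois_global(rois, psfs, link, ctrl = ctrl)
    chi2[, d] <- fits[[d]]$chi2
  }
  ok <- rowSums(matrix(vapply(fits, function(f) f$converged, logical(length(rois))),
                       ncol = nrow(ratios))) > 0
  win <- apply(chi2, 1, which.min)
  best <- do.call(rbind, lapply(seq_along(rois), function(r) {
    row <- fits[[win[r]]][r, ]
    row$dye <- ratios$label[win[r]]
    row
  }))
  best$classified <- ok
  list(dye = ratios$label[win], chi2 = chi2, fits = best, ratios = ratios)
}
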