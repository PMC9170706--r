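# Simulation benchmarks: self-contained evaluations of localization
# precision and color assignment under the standard simulated conditions.
# These drive both the test suite and the reproduction script.

#' Biplane precision benchmark: global fit vs CRLB vs individual fitting
#'
#' Simulates biplane ROIs (total photons split 1:1, Poisson noise) on the
#' default spline biplane PSF pair, fits them (a) globally with x, y, z,
#' photons and background shared and (b) per channel individually with
#' CRLB-weighted averaging of the positions, and tabulates per-z RMSE
#' against the CRLB.
#'
#' @param seed RNG seed.
#' @param n_per_z molecules per z position.
#' @param z_grid axial positions (nm).
#' @param photons total photons per molecule.
#' @param bg_total total background photons/pixel.
#' @param roi_size ROI side.
#' @param psfs optional PSF pair (default [make_biplane_spline_psfs()]).
#' @return list with `per_z` (data.frame), `ratio_mean` (mean over z of
#'   RMSE_z(individual)/RMSE_z(global)) and `crlb_halfrange` (largest
#'   symmetric half-range where x, y and z RMSE all stay within 20% of
#'   sqrt(CRLB)).
#' @export
benchmark_biplane <- function(seed = 101, n_per_z = 200,
                              z_grid = seq(-600, 600, by = 50),
                              photons = 5000, bg_total = 40, roi_size = 15,
                              psfs = NULL) {
  if (is.null(psfs)) psfs <- make_biplane_spline_psfs()
  cfg <- sim_config("biplane", photons = photons, bg_total = bg_total,
                    z_grid = z_grid, n_per_z = n_per_z,
                    roi_size = roi_size, seed = seed)
  sim <- simulate_rois(psfs, cfg)
  linkg <- link_spec(2, shared = c("x", "y", "z", "N", "bg"),
                     S = list(N = c(0.5, 0.5)))
  resg <- fit_rois_global(sim$rois, psfs, linkg)
  link1 <- link_spec(1, shared = c("x", "y", "z", "N", "bg"))
  pick <- function(roi, i) multichannel_roi(list(roi$M[[i]]), frame = roi$frame)
  res1 <- fit_rois_global(lapply(sim$rois, pick, 1), psfs[[1]], link1)
  res2 <- fit_rois_global(lapply(sim$rois, pick, 2), psfs[[2]], link1)
  safe_var <- function(v) ifelse(is.na(v) | v <= 0, Inf, v)
  comb <- crlb_weighted_average(cbind(res1$z, res2$z),
                                cbind(safe_var(res1$crlb_z),
                                      safe_var(res2$crlb_z)))
  per_z <- do.call(rbind, lapply(z_grid, function(zv) {
    sel <- sim$truth$z == zv
    data.frame(
      z = zv,
      rmse_x = sqrt(mean((resg$x[sel] - sim$truth$x[sel])^2)),
      crlb_x = sqrt(mean(resg$crlb_x[sel])),
      rmse_y = sqrt(mean((resg$y[sel] - sim$truth$y[sel])^2)),
      crlb_y = sqrt(mean(resg$crlb_y[sel])),
      rmse_z = sqrt(mean((resg$z[sel] - zv)^2)),
      crlb_z = sqrt(mean(resg$crlb_z[sel])),
      rmse_z_indiv = sqrt(mean((comb$estimate[sel] - zv)^2)))
  }))
  ratio_mean <- mean(per_z$rmse_z_indiv / per_z$rmse_z)
  ok <- per_z$rmse_x <= 1.2 * per_z$crlb_x &
    per_z$rmse_y <= 1.2 * per_z$crlb_y &
    per_z$rmse_z <= 1.2 * per_z$crlb_z
  half <- crlb_halfrange(per_z$z, ok)
  list(per_z = per_z, ratio_mean = ratio_mean, crlb_halfrange = half,
       fits_global = resg)
}

# largest L such that every |z| <= L slice satisfies ok
crlb_halfrange <- function(z, ok) {
  cand <- sort(unique(abs(z)))
  half <- 0
  for (L in cand) {
    if (all(ok[abs(z) <= L])) half <- L else break
  }
  half
}

#' 4Pi photon-linking benchmark
#'
#' Simulates four quadrature phase channels from the simplified
#' interferometric PSF and compares the axial RMSE of (a) a global fit
#' linking x, y, z and phase with per-channel photons/background against
#' (b) a fit that additionally links photons and background.
#'
#' @param seed RNG seed.
#' @param n_per_z molecules per z.
#' @param z_grid axial positions over the central interference range (nm).
#' @param photons photons per objective.
#' @param bg_total background photons/pixel per objective.
#' @param roi_size ROI side.
#' @param psf optional [fourpi_psf()].
#' @return list with `per_z`, `ratio_max` (max over z of
#'   RMSE_z(a)/RMSE_z(b))).
#' @export
benchmark_fourpi <- function(seed = 202, n_per_z = 200,
                             z_grid = seq(-400, 400, by = 50),
                             photons = 2000, bg_total = 20, roi_size = 15,
                             psf = NULL) {
  if (is.null(psf)) psf <- make_fourpi_psf()
  cfg <- sim_config("fourpi", photons = photons, bg_total = bg_total,
                    z_grid = z_grid, n_per_z = n_per_z,
                    roi_size = roi_size, xy = "uniform1", seed = seed)
  sim <- simulate_fourpi(psf, cfg)
  pp <- c("x", "y", "z", "N", "bg", "phi")
  link_a <- link_spec(4, shared = c("x", "y", "z", "phi"), params = pp)
  link_b <- link_spec(4, shared = pp, params = pp)
  res_a <- fit_rois_global(sim$rois, psf, link_a)
  res_b <- fit_rois_global(sim$rois, psf, link_b)
  per_z <- do.call(rbind, lapply(z_grid, function(zv) {
    sel <- sim$truth$z == zv
    data.frame(z = zv,
               rmse_z_a = sqrt(mean((res_a$z[sel] - zv)^2)),
               rmse_z_b = sqrt(mean((res_b$z[sel] - zv)^2)),
               crlb_z_b = sqrt(mean(res_b$crlb_z[sel])))
  }))
  list(per_z = per_z, ratio_max = max(per_z$rmse_z_a / per_z$rmse_z_b))
}

#' Paired color-assignment benchmark: threshold vs fixed-ratio ML
#'
#' Simulates a four-dye ratiometric data set, assigns colors on the
#' identical ROIs with (1) the normalized-ratio threshold method after a
#' fit with photons local and (2) fixed-photon-ratio refitting with
#' maximum-likelihood selection, and counts misclassifications.
#'
#' @param seed RNG seed.
#' @param n molecules.
#' @param ratios dye I2/I1 ratios.
#' @param photon_mean,photon_cv log-normal photon distribution.
#' @param bg_total total background photons/pixel.
#' @param z_range axial placement range (nm).
#' @return list with `confusion_threshold`, `confusion_ml`,
#'   `mis_threshold`, `mis_ml`, `truth`, `ml_dye`, `thr_dye`.
#' @export
benchmark_color <- function(seed = 303, n = 500,
                            ratios = c(0.39, 0.21, 0.07, 0.02),
                            photon_mean = 3000, photon_cv = 0.5,
                            bg_total = 40, z_range = c(-600, 600)) {
  rset <- dye_ratio_set(ratios)
  psfs <- make_astig_psfs()
  sim <- simulate_multicolor(psfs, rset, n = n, photon_mean = photon_mean,
                             photon_cv = photon_cv, bg_total = bg_total,
                             z_range = z_range, seed = seed)
  # threshold method: photons local (individual photon estimates)
  link_t <- link_spec(2, shared = c("x", "y", "z"))
  fit_t <- fit_rois_global(sim$rois, psfs, link_t)
  r <- normalized_ratio(fit_t$N_ch1, fit_t$N_ch2)
  thr_idx <- classify_threshold(r, default_boundaries(rset))
  # ML method: fixed-ratio hypotheses, bg shared
  base <- link_spec(2, shared = c("x", "y", "z", "N", "bg"))
  fr <- fit_fixed_ratio(sim$rois, psfs, rset, link_base = base)
  ml_idx <- match(fr$dye, rset$label)
  tr <- sim$truth$dye_index
  conf <- function(idx) table(factor(tr, levels = 1:4),
                              factor(idx, levels = 1:4), useNA = "ifany")
  list(confusion_threshold = conf(thr_idx), confusion_ml = conf(ml_idx),
       mis_threshold = mean(thr_idx != tr, na.rm = FALSE),
       mis_ml = mean(ml_idx != tr),
       truth = tr, ml_dye = ml_idx, thr_dye = thr_idx, ratio = r)
}

#' Calibration round-trip benchmark
#'
#' Simulates dual-channel bead stacks through a known affine transform,
#' builds the multi-channel spline calibration and validates it against
#' the nominal slice z positions.
#'
#' @param seed RNG seed.
#' @param n_beads number of beads.
#' @param z_step slice spacing (nm).
#' @param photons bead photons per slice.
#' @return list with `per_slice` (mean error per slice), `max_abs_mean_error`,
#'   `transform_rms` (mapping error vs truth over the field).
#' @export
benchmark_calibration <- function(seed = 404, n_beads = 5, z_step = 25,
                                  photons = 3e4) {
  set.seed(seed)
  gen <- list(gaussian_psf(z_range = c(-700, 700)),
              gaussian_psf(z_range = c(-700, 700)))
  A <- diag(3)
  A[1, 1] <- 1.002; A[2, 2] <- 0.998; A[1, 2] <- 0.004
  A[1, 3] <- 3.3; A[2, 3] <- -2.6
  tf_true <- channel_transform(A)
  # well-separated bead positions with sub-pixel offsets
  grid <- expand.grid(x = c(15, 32, 49), y = c(15, 32, 49))
  pick <- sample(nrow(grid), n_beads)
  bead_xy <- as.matrix(grid[pick, ]) + matrix(stats::runif(2 * n_beads, -0.5, 0.5),
                                              ncol = 2)
  zpos <- seq(-600, 600, by = z_step)
  bs <- simulate_bead_stacks(gen, tf_true, bead_xy, z_positions = zpos,
                             photons = photons, bg = 2, size = 64,
                             noise = TRUE, seed = seed)
  cal <- build_multichannel_psf(bs$stacks, z_step = z_step, roi_size = 21)
  val <- validate_calibration(cal, bs$stacks, zpos, fit_roi_size = 15,
                              z_fit_range = c(-400, 400))
  per_slice <- stats::aggregate(error ~ z_true, val, mean)
  field <- cbind(stats::runif(100, 8, 56), stats::runif(100, 8, 56))
  err <- apply_transform(cal$transforms[[2]], field) -
    apply_transform(tf_true, field)
  list(per_slice = per_slice,
       max_abs_mean_error = max(abs(per_slice$error)),
       transform_rms = sqrt(mean(rowSums(err^2))),
       calibration = cal)
}
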