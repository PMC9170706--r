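# Bead calibration: candidate detection, transform-aware ROI cutting,
# 3D registration with quality control, and the spline model round trip.

make_bead_stack <- function(positions, z_positions = seq(-300, 300, by = 50),
                            photons = 2e4, bg = 1, size = 48, noise = FALSE,
                            psf = tiny_gauss_psf()) {
  simulate_bead_stacks(list(psf), identity_transform(),
                       positions, z_positions = z_positions,
                       photons = photons, bg = bg, size = size,
                       noise = noise, seed = 1)$stacks[[1]]
}

test_that("bead candidates are local maxima away from borders", {
  zero <- array(0, c(40, 40, 5))
  expect_equal(nrow(find_bead_candidates(zero, threshold = 1,
                                         roi_size = 15)), 0)
  one <- make_bead_stack(cbind(20.2, 23.7), size = 40)
  cand <- find_bead_candidates(one, roi_size = 15)
  expect_equal(nrow(cand), 1)
  expect_equal(unname(cand[1, ]), c(20L, 24L))
  two <- make_bead_stack(cbind(c(14, 34), c(15, 32)), size = 48)
  cand2 <- find_bead_candidates(two, roi_size = 13)
  expect_equal(nrow(cand2), 2)
  expect_true(all(apply(abs(sweep(cand2, 2, c(14, 15))), 1, max) <= 1 |
                    apply(abs(sweep(cand2, 2, c(34, 32))), 1, max) <= 1))
})

test_that("ROI cutting stores residual shifts and co-centers channels", {
  psf <- tiny_gauss_psf()
  stack <- make_bead_stack(cbind(20, 20), size = 44)
  same <- cut_shifted_rois(list(stack, stack), cbind(20L, 20L),
                           roi_size = 15)
  expect_equal(same[[1]]$shifts, matrix(0, 2, 2))
  expect_equal(same[[1]]$channels[[1]], same[[1]]$channels[[2]])

  # target translated +0.3 px in x: after shifting, center of mass of the
  # target ROI matches the reference to < 0.02 px
  A <- diag(3); A[1, 3] <- 0.3
  bs <- simulate_bead_stacks(list(psf, psf), channel_transform(A),
                             cbind(20, 20), z_positions = c(-50, 0, 50),
                             photons = 2e4, bg = 0, size = 44,
                             noise = FALSE, seed = 2)
  rois <- cut_shifted_rois(bs$stacks, cbind(20L, 20L),
                           list(NULL, channel_transform(A)), roi_size = 15)
  expect_equal(rois[[1]]$shifts[2, ], c(0.3, 0), tolerance = 1e-12)
  com <- function(m) {
    u <- 0:(nrow(m) - 1); tot <- sum(m)
    c(sum(t(m) * u), sum(m * u)) / tot
  }
  c_ref <- com(rois[[1]]$channels[[1]][, , 2])
  c_tgt <- com(rois[[1]]$channels[[2]][, , 2])
  expect_lt(max(abs(c_ref - c_tgt)), 0.02)

  # out-of-bounds candidates are skipped with a warning
  expect_warning(
    out <- cut_shifted_rois(list(stack), cbind(2L, 2L), roi_size = 15),
    "out of bounds")
  expect_equal(length(out), 0)
})

test_that("mirrored target channels are flipped before shifting", {
  psf <- tiny_gauss_psf()
  size <- 41
  # bead offset +1 px in x from the ROI center in the target channel
  stack_t <- make_bead_stack(cbind(21, 20), size = size)
  stack_r <- make_bead_stack(cbind(20, 20), size = size)
  M <- diag(3); M[1, 1] <- -1; M[1, 3] <- size - 1 # x -> (size-1) - x
  tf <- channel_transform(M, mirror_axis = "x")
  rois <- cut_shifted_rois(list(stack_r, stack_t), cbind(20L, 20L),
                           list(NULL, tf), roi_size = 15)
  # reference ROI: bead at center; mirrored target ROI: the +1 px offset
  # appears at -1 px before shifting; here s = 0, so it stays at -1
  sl <- rois[[1]]$channels[[2]][, , 7]
  peak <- which(sl == max(sl), arr.ind = TRUE)
  expect_equal(unname(peak[1, "col"]) - 8, -1)
})

test_that("3D registration recovers shifts, rejects outliers, conserves flux", {
  psf <- tiny_gauss_psf()
  base <- make_bead_stack(cbind(20, 20), size = 41)
  roi_of <- function(st) list(channels = list(st), shifts = matrix(0, 1, 2),
                              position = c(20L, 20L))
  crop <- function(st) cut_shifted_rois(list(st), cbind(20L, 20L),
                                        roi_size = 15)[[1]]
  identical3 <- list(crop(base), crop(base), crop(base))
  reg <- register_beads_3d(identical3, n_iter = 1)
  expect_true(all(reg$accepted))
  expect_lt(max(abs(reg$shifts)), 1e-6)
  expect_rel_close(reg$template[[1]], identical3[[1]]$channels[[1]], 1e-9)

  # a bead shifted by one voxel in x is recovered
  shifted <- make_bead_stack(cbind(21, 20), size = 41)
  reg2 <- register_beads_3d(list(crop(base), crop(base), crop(shifted)),
                            n_iter = 1, cutoff = 0.5)
  # shifts are relative to the (average) template; the displacement of the
  # shifted bead relative to the identical pair is the constructed 1 voxel
  expect_equal(unname(reg2$shifts[3, 1] - mean(reg2$shifts[1:2, 1])), 1,
               tolerance = 0.1)

  # a pure-noise bead is rejected at the default cutoff
  set.seed(9)
  noise <- array(runif(15 * 15 * 13, 0, 50), c(15, 15, 13))
  reg3 <- register_beads_3d(list(crop(base), crop(base),
                                 list(channels = list(noise),
                                      shifts = matrix(0, 1, 2),
                                      position = c(20L, 20L))),
                            n_iter = 2, cutoff = 0.9)
  expect_false(reg3$accepted[3])
  expect_true(all(reg3$accepted[1:2]))

  # registration conserves flux for interior content
  tmpl_sum <- sum(reg$template[[1]])
  mean_sum <- mean(vapply(identical3, function(r)
    sum(r$channels[[1]]), numeric(1)))
  expect_lt(abs(tmpl_sum - mean_sum) / mean_sum, 1e-6)

  expect_error(register_beads_3d(identical3, cutoff = 1.1),
               "all beads rejected")
})

test_that("full calibration reproduces the generating model and validates", {
  bench <- benchmark_calibration(seed = 404, n_beads = 5, z_step = 50,
                                 photons = 2e4)
  expect_lt(bench$max_abs_mean_error, 5)
  expect_lt(bench$transform_rms, 0.05)
  cal <- bench$calibration
  # normalization: central slice of the reference model sums to 1
  nz <- cal$psfs[[1]]$dim[["nz"]]
  zc <- (cal$psfs[[1]]$z0_index - 1) * 0
  n <- cal$psfs[[1]]$dim[["nx"]]
  ctr <- (n - 1) / 2
  v <- evaluate_channel(cal$psfs[[1]],
                        list(x = ctr, y = ctr, z = 0, N = 1, bg = 0), n)
  expect_equal(sum(v), 1, tolerance = 0.02)
  # z = 0 slice fits close to zero
  sl0 <- bench$per_slice[which.min(abs(bench$per_slice$z_true)), ]
  expect_lt(abs(sl0$error), 5)
})

test_that("identical channels give identical models; empty validation is empty", {
  psf <- tiny_gauss_psf()
  stack <- make_bead_stack(cbind(c(14.2, 33.6, 14.8), c(15.1, 14.6, 33.2)),
                           size = 48)
  cal <- build_multichannel_psf(list(stack, stack), z_step = 50,
                                transforms = list(identity_transform(),
                                                  identity_transform()),
                                roi_size = 15)
  expect_rel_close(cal$psfs[[1]]$coef, cal$psfs[[2]]$coef, 1e-6)
  empty <- validate_calibration(cal, list(stack, stack),
                                seq(-300, 300, by = 50),
                                beads = matrix(integer(0), 0, 2))
  expect_equal(nrow(empty), 0)
})
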