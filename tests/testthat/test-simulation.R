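# Synthetic-data generator: determinism, Poisson statistics, photon
# accounting across channels and modalities, and the bead-stack fixtures.

test_that("a fixed seed reproduces the simulation bit for bit", {
  psfs <- make_astig_psfs()
  cfg <- sim_config("biplane", photons = 2000, bg_total = 20,
                    z_grid = c(-100, 100), n_per_z = 3, roi_size = 11,
                    seed = 9)
  a <- simulate_rois(psfs, cfg)
  b <- simulate_rois(psfs, cfg)
  expect_identical(a$truth, b$truth)
  for (r in seq_along(a$rois))
    expect_identical(a$rois[[r]]$M, b$rois[[r]]$M)

  fp <- make_fourpi_psf()
  cf <- sim_config("fourpi", photons = 1000, bg_total = 10,
                   z_grid = c(0), n_per_z = 3, roi_size = 11,
                   xy = "uniform1", seed = 4)
  f1 <- simulate_fourpi(fp, cf)
  f2 <- simulate_fourpi(fp, cf)
  expect_identical(f1$rois[[2]]$M, f2$rois[[2]]$M)

  bs1 <- simulate_bead_stacks(make_astig_psfs(), identity_transform(),
                              cbind(20, 20), z_positions = c(-50, 0, 50),
                              photons = 1e4, size = 40, seed = 3)
  bs2 <- simulate_bead_stacks(make_astig_psfs(), identity_transform(),
                              cbind(20, 20), z_positions = c(-50, 0, 50),
                              photons = 1e4, size = 40, seed = 3)
  expect_identical(bs1$stacks, bs2$stacks)
})

test_that("pixel draws follow the Poisson law around the expected image", {
  psfs <- make_astig_psfs()
  cfg <- sim_config("astig2color", photons = 2000, bg_total = 20,
                    z_grid = rep(0, 1), n_per_z = 10000, roi_size = 5,
                    seed = 2)
  sim <- simulate_rois(psfs, cfg)
  mu <- evaluate_channel(psfs[[1]], list(x = 2, y = 2, z = 0, N = 1000,
                                         bg = 10), 5)
  px <- vapply(sim$rois, function(r) r$M[[1]][3, 3], numeric(1))
  se <- sqrt(mu[3, 3] / length(px))
  expect_lt(abs(mean(px) - mu[3, 3]), 3 * se)
  # variance equals the mean for Poisson pixels (within sampling error)
  expect_lt(abs(var(px) - mu[3, 3]) / mu[3, 3], 0.1)
})

test_that("biplane photon budget splits 1:1 with the stated totals", {
  psfs <- make_biplane_spline_psfs()
  cfg <- sim_config("biplane", photons = 5000, bg_total = 40,
                    z_grid = c(0), n_per_z = 200, roi_size = 15, seed = 5)
  sim <- simulate_rois(psfs, cfg)
  expect_true(all(sim$truth$N_ch1 == 2500, sim$truth$N_ch2 == 2500,
                  sim$truth$bg == 20))
  # recovered by summing M - bg over molecules; the expectation is the
  # in-ROI PSF mass times 2500 (part of a defocused PSF falls outside)
  s1 <- mean(vapply(sim$rois, function(r) sum(r$M[[1]]) - 20 * 225,
                    numeric(1)))
  mu1 <- evaluate_channel(psfs[[1]], list(x = 7, y = 7, z = 0, N = 2500,
                                          bg = 20), 15)
  expected <- sum(mu1) - 20 * 225
  expect_lt(abs(s1 - expected) / 2500, 0.02)
  expect_gt(expected / 2500, 0.8)
})

test_that("multicolor splits follow the dye ratios and the stated r values", {
  rset <- dye_ratio_set(c(0.39, 0.21, 0.07, 0.02))
  expect_equal(ratio_from_dye(c(0.39, 0.21, 0.07, 0.02)),
               c(0.439, 0.653, 0.869, 0.961), tolerance = 5e-4)
  psfs <- make_astig_psfs()
  sim <- simulate_multicolor(psfs, rset, n = 4000, photon_mean = 3000,
                             photon_cv = 0.5, seed = 6)
  for (d in 1:4) {
    sel <- sim$truth$dye_index == d
    emp <- mean(sim$truth$N_ch2[sel] / sim$truth$N_ch1[sel])
    expect_lt(abs(emp - rset$r[d]) / max(rset$r[d], 1e-9), 0.02)
  }
  # ratio-zero dye puts all photons in channel 1
  sim0 <- simulate_multicolor(psfs, dye_ratio_set(0), n = 10, seed = 1)
  expect_true(all(sim0$truth$N_ch2 == 0))
  # truth join is lossless
  expect_equal(length(sim$rois), nrow(sim$truth))
})

test_that("interferometric channels have the quadrature photon structure", {
  fp <- make_fourpi_psf(m = 0.9)
  cfg <- sim_config("fourpi", photons = 2000, bg_total = 20,
                    z_grid = rep(0, 1), n_per_z = 400, roi_size = 15,
                    xy = "center", seed = 7)
  sim <- simulate_fourpi(fp, cfg)
  expect_true(all(sim$truth$N_channel == 1000, sim$truth$bg == 10))
  # z = 0, phi = 0: expected channel sums proportional to 1 + m cos(offset)
  sums <- sapply(1:4, function(i)
    mean(vapply(sim$rois, function(r) sum(r$M[[i]]) - 10 * 225, numeric(1))))
  fac <- 1 + 0.9 * cos(fp$offsets)
  expect_lt(max(abs(sums / sums[1] - fac / fac[1])), 0.05)

  # m = 0: the four channels are statistically identical
  fp0 <- make_fourpi_psf(m = 0)
  sim0 <- simulate_fourpi(fp0, sim_config("fourpi", photons = 1000,
                                          bg_total = 10, z_grid = rep(50, 1),
                                          n_per_z = 50, roi_size = 11,
                                          seed = 8))
  pool <- lapply(1:4, function(i)
    unlist(lapply(sim0$rois, function(r) r$M[[i]])))
  expect_gt(suppressWarnings(stats::ks.test(pool[[1]],
                                            pool[[3]]))$p.value, 0.01)
  expect_lt(abs(mean(pool[[2]]) - mean(pool[[4]])) / mean(pool[[4]]), 0.02)
})

test_that("photon conservation in expectation for every split rule", {
  psfs <- make_astig_psfs()
  for (split in list(c(0.5, 0.5), c(0.8, 0.2))) {
    cfg <- sim_config("astig2color", photons = 3000, split = split,
                      bg_total = 20, z_grid = c(0), n_per_z = 2, seed = 3)
    sim <- simulate_rois(psfs, cfg)
    expect_equal(sim$truth$N_ch1 + sim$truth$N_ch2,
                 rep(3000, nrow(sim$truth)))
  }
  expect_error(sim_config("astig2color", photons = -5), "photons")
})

test_that("bead fixtures respect the transform and warn on crowding", {
  psfs <- make_astig_psfs()
  A <- diag(3); A[1, 3] <- 5.3
  bs <- simulate_bead_stacks(psfs, channel_transform(A),
                             cbind(15.2, 20.4), z_positions = c(0),
                             photons = 1e5, bg = 0, size = 40,
                             noise = FALSE, seed = 2)
  com <- function(m) {
    u <- 0:(nrow(m) - 1); c(sum(t(m) * u), sum(m * u)) / sum(m)
  }
  c1 <- com(bs$stacks[[1]][, , 1])
  c2 <- com(bs$stacks[[2]][, , 1])
  expect_equal(c2[1] - c1[1], 5.3, tolerance = 0.05)
  expect_warning(simulate_bead_stacks(psfs, channel_transform(A),
                                      rbind(c(20, 20), c(24, 20)),
                                      z_positions = c(0), size = 40,
                                      seed = 1), "overlap")
})
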