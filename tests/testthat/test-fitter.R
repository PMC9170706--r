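# Global fitter: objective, score/Hessian assembly against independent
# oracles, L-M updates, initialization, convergence, CRLB and the linked
# information structure.

test_that("Poisson deviance has the stated pointwise values", {
  M <- matrix(c(2, 5, 1), 1)
  expect_equal(mle_objective(M, M), 0)
  expect_equal(mle_objective(matrix(0), matrix(3)), 6)
  expect_equal(mle_objective(matrix(1), matrix(2)), 2 * (1 - log(2)))
  expect_error(mle_objective(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("score vanishes at an exact fit and adds over identical channels", {
  psf <- tiny_gauss_psf()
  link2 <- link_spec(2, shared = c("x", "y", "z", "N", "bg"))
  theta <- c(x = 6.2, y = 5.8, z = 80, N = 1200, bg = 9)
  mu <- evaluate_channel(psf, as.list(theta), 13)
  roi <- multichannel_roi(list(mu, mu))
  jh <- assemble_jacobian_hessian(roi, psf, theta, link2)
  expect_lt(max(abs(jh$J)), 1e-7)

  set.seed(8)
  M <- matrix(rpois(169, mu), 13, 13)
  roi1 <- multichannel_roi(list(M))
  link1 <- link_spec(1, shared = c("x", "y", "z", "N", "bg"))
  jh1 <- assemble_jacobian_hessian(roi1, psf, theta, link1)
  roi2 <- multichannel_roi(list(M, M))
  jh2 <- assemble_jacobian_hessian(roi2, psf, theta, link2)
  expect_equal(jh2$J, 2 * jh1$J, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(jh2$H, 2 * jh1$H, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("assembled score and Hessian match finite-difference and loop oracles", {
  set.seed(33)
  psf <- tiny_gauss_psf()
  psfs <- list(psf, psf)
  link <- link_spec(2, shared = c("x", "y", "z"), S = list(x = c(1, 1)))
  shifts <- matrix(c(0, 0, 0.3, -0.2), 2, 2, byrow = TRUE)
  theta <- setNames(numeric(link$n_global), link$gnames)
  theta["x"] <- 6.3; theta["y"] <- 5.7; theta["z"] <- -120
  theta[c("N_ch1", "N_ch2")] <- c(1500, 900)
  theta[c("bg_ch1", "bg_ch2")] <- c(12, 8)
  Mlist <- lapply(1:2, function(i) {
    th <- globfit:::link_channel_params(link, theta, shifts)[, i]
    matrix(rpois(169, evaluate_channel(psf, as.list(th), 13)), 13, 13)
  })
  roi <- multichannel_roi(Mlist, shifts = shifts)
  jh <- assemble_jacobian_hessian(roi, psfs, theta, link)

  # finite differences of the deviance: J = -(1/2) d(chi2)/d(theta)
  chi2_of <- function(tt) {
    th <- globfit:::link_channel_params(link, tt, shifts)
    sum(vapply(1:2, function(i)
      mle_objective(Mlist[[i]],
                    evaluate_channel(psf, as.list(th[, i]), 13)),
      numeric(1)))
  }
  for (g in seq_along(theta)) {
    h <- if (grepl("^N", names(theta)[g])) 1e-1 else
      if (grepl("^z", names(theta)[g])) 1e-2 else 1e-4
    tp <- theta; tp[g] <- tp[g] + h
    tm <- theta; tm[g] <- tm[g] - h
    fd <- -(chi2_of(tp) - chi2_of(tm)) / (4 * h)
    expect_lt(abs(fd - jh$J[g]) / max(abs(jh$J)), 1e-4)
  }

  # brute-force loop oracle for the Hessian form, including the zeroed
  # local-local cross entries
  ng <- link$n_global
  Horacle <- matrix(0, ng, ng)
  for (i in 1:2) {
    th <- globfit:::link_channel_params(link, theta, shifts)[, i]
    ed <- evaluate_derivatives(psf, as.list(th), 13)
    for (m in seq_len(ng)) for (n in seq_len(ng)) {
      nm_m <- names(theta)[m]; nm_n <- names(theta)[n]
      base_m <- sub("_ch[0-9]+$", "", nm_m)
      base_n <- sub("_ch[0-9]+$", "", nm_n)
      ch_m <- if (grepl("_ch", nm_m)) as.integer(sub(".*_ch", "", nm_m)) else 0L
      ch_n <- if (grepl("_ch", nm_n)) as.integer(sub(".*_ch", "", nm_n)) else 0L
      if (ch_m > 0 && ch_m != i) next
      if (ch_n > 0 && ch_n != i) next
      if (ch_m > 0 && ch_n > 0 && m != n) next # printed local-local rule
      sm <- if (ch_m == 0) link$S[base_m, i] else 1
      sn <- if (ch_n == 0) link$S[base_n, i] else 1
      Horacle[m, n] <- Horacle[m, n] +
        sum(sm * ed$D[, base_m] * sn * ed$D[, base_n] *
              as.vector(Mlist[[i]]) / ed$mu^2)
    }
  }
  expect_rel_close(jh$H, Horacle, 1e-10)
  expect_equal(jh$H, t(jh$H), tolerance = 1e-12)
})

test_that("damped update solves the stated linear system", {
  H <- diag(c(2, 4)); J <- c(2, 4)
  expect_equal(lm_step(J, H, 0), c(1, 1), tolerance = 1e-9)
  # large damping: step magnitude ~ J / (lambda * diag(H))
  big <- lm_step(J, H, 1e8)
  expect_equal(big, J / (1e8 * diag(H)), tolerance = 1e-6)
  set.seed(2)
  A <- crossprod(matrix(rnorm(25), 5))
  J5 <- rnorm(5)
  expect_equal(lm_step(J5, A, 1),
               solve(A + diag(diag(A)), J5), tolerance = 1e-8)
})

test_that("initial estimates recover position, photons and background", {
  psf <- tiny_gauss_psf()
  link <- link_spec(2, shared = c("x", "y", "z", "N", "bg"),
                    S = list(N = c(0.5, 0.5)))
  expect_error(initial_estimates(
    multichannel_roi(list(matrix(0, 13, 13), matrix(0, 13, 13))),
    list(psf, psf), link), "degenerate")

  flat <- multichannel_roi(list(matrix(4, 13, 13), matrix(4, 13, 13)))
  t_flat <- initial_estimates(flat, list(psf, psf), link)
  expect_equal(unname(t_flat["bg"]), 4)
  expect_equal(unname(t_flat["N"]), 2) # floored at 1 per channel

  set.seed(5)
  mu <- evaluate_channel(psf, list(x = 6, y = 6, z = 0, N = 1000, bg = 10), 13)
  roi <- multichannel_roi(list(matrix(rpois(169, mu), 13),
                               matrix(rpois(169, mu), 13)))
  t0 <- initial_estimates(roi, list(psf, psf), link)
  expect_lt(abs(t0[["x"]] - 6), 0.3)
  expect_lt(abs(t0[["y"]] - 6), 0.3)
  expect_lt(abs(t0[["N"]] - 2000) / 2000, 0.2)
})

test_that("noiseless ROIs are a fixed point of the fit", {
  psf <- tiny_gauss_psf()
  link <- link_spec(2, shared = c("x", "y", "z", "N", "bg"),
                    S = list(N = c(0.5, 0.5)))
  truth <- c(x = 6.4, y = 5.6, z = 150, N = 5000, bg = 20)
  mu <- lapply(1:2, function(i)
    evaluate_channel(psf, list(x = truth[["x"]], y = truth[["y"]],
                               z = truth[["z"]], N = truth[["N"]] / 2,
                               bg = truth[["bg"]]), 13))
  roi <- multichannel_roi(mu)
  t0 <- truth + c(0.3, -0.3, 50, 300, 2)
  res <- fit_rois_global(list(roi), list(psf, psf), link,
                         theta0 = matrix(t0, 1,
                                         dimnames = list(NULL, names(truth))),
                         ctrl = fit_controls(z_starts = t0[["z"]]))
  for (nm in names(truth))
    expect_lt(abs(res[[nm]] - truth[[nm]]),
              1e-6 * max(1, abs(truth[[nm]])))
  expect_true(res$converged)
})

test_that("L-M optimum matches an exhaustive grid + polish oracle", {
  # 5x5 two-channel toy ROIs with only x and N free; the remaining
  # parameters are pinned through the linking (scale 0 + fixed translation)
  psf <- gaussian_psf(sigma0 = c(1.0, 1.0), gamma = c(0, 0), d = 1e9,
                      z_range = c(-1, 1))
  link <- link_spec(2, shared = c("x", "y", "z", "N", "bg"),
                    S = list(N = c(0.5, 0.5), y = c(0, 0), z = c(0, 0),
                             bg = c(0, 0)),
                    delta = list(y = c(2, 2), z = c(0, 0), bg = c(3, 3)))
  set.seed(12)
  for (case in 1:3) {
    xt <- runif(1, 1.6, 2.4); Nt <- runif(1, 300, 800)
    Mlist <- lapply(1:2, function(i)
      matrix(rpois(25, evaluate_channel(psf, list(x = xt, y = 2, z = 0,
                                                  N = Nt / 2, bg = 3), 5)),
             5, 5))
    roi <- multichannel_roi(Mlist)
    chi2_xy <- function(x, N) {
      sum(vapply(1:2, function(i)
        mle_objective(Mlist[[i]],
                      evaluate_channel(psf, list(x = x, y = 2, z = 0,
                                                 N = N / 2, bg = 3), 5)),
        numeric(1)))
    }
    # oracle: coarse grid then local optim polish
    grid <- expand.grid(x = seq(1, 3, by = 0.05),
                        N = seq(100, 1200, by = 25))
    gc2 <- mapply(chi2_xy, grid$x, grid$N)
    start <- grid[which.min(gc2), ]
    pol <- optim(c(start$x, start$N),
                 function(p) chi2_xy(p[1], p[2]),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    theta0 <- setNames(c(2, 2, 0, 500, 3), link$gnames)
    res <- fit_rois_global(list(roi), list(psf, psf), link,
                           theta0 = matrix(theta0, 1,
                                           dimnames = list(NULL,
                                                           names(theta0))),
                           ctrl = fit_controls(z_starts = 0, tol = 1e-10))
    expect_lt(abs(res$x - pol$par[1]), 1e-3)
    expect_lt(abs(res$N - pol$par[2]), 1e-3 * pol$par[2])
  }
})

test_that("CRLB shows the classic Gaussian limit and information additivity", {
  sig <- 1.5
  psf <- gaussian_psf(sigma0 = c(sig, sig), gamma = c(100, -100), d = 400,
                      z_range = c(-500, 500))
  link1 <- link_spec(1, shared = c("x", "y", "z", "N", "bg"))
  # bg -> 0, large ROI: CRLB_x -> sigma_x(z)^2 / N within 5%
  N <- 2000
  th <- c(x = 12, y = 12, z = 0, N = N, bg = 1e-9)
  sig_z <- gaussian_sigma_z(psf, 0, 1)$sigma
  cr <- compute_crlb(psf, th, link1, roi_size = 25)
  expect_lt(abs(cr[["crlb_x"]] - sig_z^2 / N) / (sig_z^2 / N), 0.05)
  th2 <- th; th2[["N"]] <- 2 * N
  cr2 <- compute_crlb(psf, th2, link1, roi_size = 25)
  expect_equal(cr2[["crlb_x"]], cr[["crlb_x"]] / 2, tolerance = 1e-6)
  expect_equal(cr2[["crlb_y"]], cr[["crlb_y"]] / 2, tolerance = 1e-6)

  # two identical channels, everything shared (S = 1): information doubles
  link2 <- link_spec(2, shared = c("x", "y", "z", "N", "bg"))
  cr3 <- compute_crlb(list(psf, psf), th, link2, roi_size = 25)
  expect_equal(cr3[["crlb_x"]], cr[["crlb_x"]] / 2, tolerance = 1e-6)

  # z-flat model: a local z parameter is unidentifiable
  flat <- gaussian_psf(sigma0 = c(sig, sig), gamma = c(0, 0), d = 1e9,
                       z_range = c(-1, 1))
  link_loc <- link_spec(1, shared = c("x", "y", "N"))
  thl <- setNames(numeric(link_loc$n_global), link_loc$gnames)
  thl["x"] <- 12; thl["y"] <- 12; thl["N"] <- N
  thl["z_ch1"] <- 0; thl["bg_ch1"] <- 1e-9
  expect_error(compute_crlb(flat, thl, link_loc, roi_size = 25),
               "unidentifiable|singular")
})

test_that("CRLB-weighted averaging follows the stated arithmetic", {
  eq <- crlb_weighted_average(c(3, 5), c(2, 2))
  expect_equal(eq$estimate, 4)
  expect_equal(eq$variance, 1)
  lim <- crlb_weighted_average(c(3, 99), c(2, Inf))
  expect_equal(lim$estimate, 3)
  ex <- crlb_weighted_average(c(10, 14), c(1, 3))
  expect_equal(ex$estimate, 11)
  expect_equal(ex$variance, 0.75)
  expect_error(crlb_weighted_average(c(1, 2), c(-1, 1)), "positive")
  expect_error(crlb_weighted_average(c(1, 2), c(Inf, Inf)), "undefined|infinite")
})

test_that("accepted L-M iterations never increase the deviance and end stationary", {
  set.seed(14)
  psf <- tiny_gauss_psf()
  link <- link_spec(2, shared = c("x", "y", "z", "N", "bg"),
                    S = list(N = c(0.5, 0.5)))
  cfg <- sim_config("biplane", photons = 4000, bg_total = 30,
                    z_grid = c(-150, 100), n_per_z = 5, roi_size = 13,
                    seed = 14)
  sim <- simulate_rois(list(psf, psf), cfg)
  res <- fit_rois_global(sim$rois, list(psf, psf), link)
  expect_true(all(res$converged))
  for (r in seq_along(sim$rois)) {
    theta <- unlist(res[r, link$gnames])
    jh <- assemble_jacobian_hessian(sim$rois[[r]], list(psf, psf),
                                    theta, link)
    # scaled stationarity: score small relative to curvature scale
    expect_lt(max(abs(jh$J) / sqrt(pmax(diag(jh$H), 1e-12))), 1e-2)
    # monotonicity: chi2 at the optimum does not exceed chi2 at the start
    t0 <- initial_estimates(sim$rois[[r]], list(psf, psf), link)
    jh0 <- assemble_jacobian_hessian(sim$rois[[r]], list(psf, psf),
                                     globfit:::clamp_theta(
                                       t0, globfit:::link_bounds(
                                         link, list(psf, psf), 13)), link)
    expect_lte(res$chi2[r], jh0$chi2 + 1e-9)
  }
})

test_that("linked-information ordering holds across configurations", {
  psf <- tiny_gauss_psf()
  psfs <- list(psf, psf)
  pp <- c("x", "y", "z", "N", "bg")
  link_all <- link_spec(2, shared = pp, S = list(N = c(0.5, 0.5)))
  link_xyz <- link_spec(2, shared = c("x", "y", "z"))
  link_one <- link_spec(1, shared = pp)
  for (zv in c(-300, -100, 0, 100, 300)) {
    th_all <- c(x = 6, y = 6, z = zv, N = 5000, bg = 20)
    c_all <- compute_crlb(psfs, th_all, link_all, roi_size = 13)[["crlb_z"]]
    th_xyz <- setNames(numeric(link_xyz$n_global), link_xyz$gnames)
    th_xyz["x"] <- 6; th_xyz["y"] <- 6; th_xyz["z"] <- zv
    th_xyz[paste0("N_ch", 1:2)] <- 2500
    th_xyz[paste0("bg_ch", 1:2)] <- 20
    c_xyz <- compute_crlb(psfs, th_xyz, link_xyz, roi_size = 13)[["crlb_z"]]
    th1 <- c(x = 6, y = 6, z = zv, N = 2500, bg = 20)
    c1 <- compute_crlb(psf, th1, link_one, roi_size = 13)[["crlb_z"]]
    comb <- 1 / (2 / c1)
    expect_lte(c_all, c_xyz + 1e-12)
    expect_lte(c_xyz, comb + 1e-12)
  }
})

test_that("fixed-ratio fitting selects the generating dye and breaks ties first", {
  set.seed(31)
  psfs <- make_astig_psfs()
  rset <- dye_ratio_set(c(0.39, 0.21, 0.07, 0.02),
                        labels = c("DY634", "AF647", "CF660C", "CF680"))
  sim <- simulate_multicolor(psfs, rset, n = 40, photon_mean = 3000,
                             photon_cv = 0, bg_total = 40,
                             z_range = c(-200, 200), seed = 31,
                             priors = c(0, 1, 0, 0)) # all AF647 (0.21)
  fr <- fit_fixed_ratio(sim$rois, psfs, rset)
  expect_gte(mean(fr$dye == "AF647"), 0.95)

  # single-hypothesis set equals a plain global fit with those scales
  one <- fit_fixed_ratio(sim$rois[1:3], psfs, dye_ratio_set(0.21))
  link <- link_spec(2, shared = c("x", "y", "z", "N", "bg"),
                    S = list(N = c(1 / 1.21, 0.21 / 1.21)))
  direct <- fit_rois_global(sim$rois[1:3], psfs, link)
  expect_equal(unname(one$chi2[, 1]), direct$chi2, tolerance = 1e-8)

  # duplicated hypotheses: deterministic tie-break to the first
  dup <- fit_fixed_ratio(sim$rois[1:3], psfs,
                         dye_ratio_set(c(0.21, 0.21), c("first", "second")))
  expect_true(all(dup$dye == "first"))
})
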