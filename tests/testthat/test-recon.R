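test_that("the truth is a fixed point of the MLEM activity update on noiseless data", {
  sim <- fx_small_noiseless()
  upd <- mlem_activity_update(sim$truth$activity, sim$truth$mu, sim$data,
                              subset = 1L, n_subsets = 1L)
  rel <- abs(upd - sim$truth$activity) / pmax(sim$truth$activity, 1e-12)
  expect_lt(max(rel[sim$truth$activity > 0]), 1e-9)
})

test_that("zero activity is absorbing for MLEM and negative data are rejected", {
  sim <- fx_small_noisy()
  g <- small_geom()
  zero <- matrix(0, g$grid_n, g$grid_n)
  upd <- mlem_activity_update(zero, sim$truth$mu, sim$data, 1L, 1L)
  expect_true(all(upd == 0))
  bad <- sim$data
  bad$counts[1] <- -1
  expect_error(mlem_activity_update(sim$truth$activity, sim$truth$mu, bad),
               "negative")
})

test_that("single-subset MLEM has nondecreasing Poisson log-likelihood", {
  sim <- fx_small_noisy()
  g <- small_geom()
  lambda <- matrix(0, g$grid_n, g$grid_n)
  lambda[mlaapet:::fov_mask(g)] <- 1
  ll <- numeric(20)
  for (k in 1:20) {
    lambda <- mlem_activity_update(lambda, sim$truth$mu, sim$data, 1L, 1L)
    ybar <- forward_project(lambda, sim$truth$mu, g,
                            additive = sim$data$additive,
                            calib = sim$data$calib)
    ll[k] <- poisson_loglik(sim$data$counts, ybar)
  }
  expect_true(all(diff(ll) > -abs(ll[1]) * 1e-10))
})

test_that("the truth is a stationary point of the MLTR attenuation update", {
  sim <- fx_small_noiseless()
  upd <- mltr_attenuation_update(sim$truth$mu, sim$truth$activity, sim$data,
                                 1L, 1L)
  expect_lt(max(abs(upd - sim$truth$mu)), 1e-9 * max(sim$truth$mu))
})

test_that("MLTR raises mu along contributing rays when ybar exceeds the data", {
  sim <- fx_small_noiseless()
  low <- 0.5 * sim$truth$mu  # under-attenuated model => ybar > y
  upd <- mltr_attenuation_update(low, sim$truth$activity, sim$data, 1L, 1L)
  body <- sim$truth$mu > 0
  expect_gt(mean(upd[body] - low[body]), 0)
  expect_true(all(upd >= 0))
})

test_that("MLTR equals a finite-difference Newton step on a one-pixel problem", {
  g <- pet_geometry(n_radial = 3, n_angles = 2, radial_spacing = 15,
                    fov_diameter = 30, n_tof_bins = 3, tof_bin_width = 30,
                    tof_resolution_ps = 200, grid_n = 1, pixel_size = 30)
  act <- matrix(5, 1, 1)
  mu0 <- 0.08
  ybar_true <- forward_project(act, matrix(0.11, 1, 1), g)
  data <- tof_sinogram(ybar_true * 1.3, NULL, 1, g)
  upd <- mltr_attenuation_update(matrix(mu0, 1, 1), act, data, 1L, 1L)
  loglik_mu <- function(m) {
    ybar_nt <- apply(forward_project(act, matrix(m, 1, 1), g), c(1, 2), sum)
    y_nt <- apply(data$counts, c(1, 2), sum)
    pos <- ybar_nt > 0
    sum(y_nt[pos] * log(ybar_nt[pos])) - sum(ybar_nt)
  }
  # Richardson-extrapolated central differences (O(h^4))
  fd <- function(h) {
    g <- (loglik_mu(mu0 + h) - loglik_mu(mu0 - h)) / (2 * h)
    hh <- (loglik_mu(mu0 + h) - 2 * loglik_mu(mu0) + loglik_mu(mu0 - h)) / h^2
    c(g, hh)
  }
  d1 <- fd(1e-3)
  d2 <- fd(5e-4)
  rich <- (4 * d2 - d1) / 3
  expect_equal(upd[1, 1], mu0 + rich[1] / (-rich[2]), tolerance = 1e-8)
})

test_that("frozen pixels are not touched by MLTR", {
  sim <- fx_small_noiseless()
  g <- small_geom()
  low <- 0.5 * sim$truth$mu
  frozen <- matrix(FALSE, g$grid_n, g$grid_n)
  frozen[1:20, ] <- TRUE
  upd <- mltr_attenuation_update(low, sim$truth$activity, sim$data, 1L, 1L,
                                 frozen = frozen)
  expect_identical(upd[1:20, ], low[1:20, ])
})

test_that("exclusion mask is empty for clean maps and covers implants", {
  g <- pet_geometry()
  water <- rasterize_phantom(make_uniform_cylinder(geometry = g), g)$mu
  expect_false(any(exclusion_mask_from_mu(water, c(0.02, 0.2))))
  expect_false(any(exclusion_mask_from_mu(water, c(0, Inf))))
  tr <- rasterize_phantom(make_torso_phantom(11, g), g)
  spec <- mismatch_spec("metal", inflation = 3)
  corrupted <- corrupt_mu_map(tr$mu, spec, g)
  mask <- exclusion_mask_from_mu(corrupted, c(0.02, 0.2))
  imp <- mlaapet:::region_mask(spec$implant, g)
  inflated <- imp & corrupted > 0.2
  expect_true(all(mask[inflated]))
})

test_that("scale constraint rescales the masked total exactly", {
  g <- small_geom()
  set.seed(8)
  act <- matrix(runif(g$grid_n^2), g$grid_n)
  mask <- matrix(FALSE, g$grid_n, g$grid_n)
  mask[1:10, ] <- TRUE
  target <- 12.34
  out <- apply_scale_constraint(act, target, g, mask)
  total <- sum(out[!mask]) * g$pixel_size^3 / 1000
  expect_lt(abs(total - target) / target, 1e-12)
  # already at target: unchanged; at half target: doubled
  cur <- sum(act[!mask]) * g$pixel_size^3 / 1000
  expect_equal(apply_scale_constraint(act, cur, g, mask), act)
  expect_equal(apply_scale_constraint(act, 2 * cur, g, mask), 2 * act)
  expect_error(apply_scale_constraint(0 * act, 1, g), "zero")
})

test_that("total-activity prior recovers the truth total on the cylinder", {
  sim <- fx_small_noiseless()
  g <- small_geom()
  ctl <- recon_control(n_subsets = 4, track_loglik = FALSE)
  prior <- compute_total_activity_prior(sim$data, sim$truth$mu, ctl)
  truth_total <- sum(sim$truth$activity) * g$pixel_size^3 / 1000
  expect_lt(abs(prior - truth_total) / truth_total, 0.01)
  zero_data <- tof_sinogram(array(0, dim(sim$data$counts)), NULL, 1, g)
  expect_equal(compute_total_activity_prior(zero_data, sim$truth$mu, ctl), 0)
})

test_that("Gaussian post-filter: identity at zero, correct FWHM, mass conserving", {
  g <- pet_geometry()
  img <- matrix(0, g$grid_n, g$grid_n)
  img[96, 96] <- 1
  expect_identical(gaussian_postfilter(img, 0, g$pixel_size), img)
  f <- gaussian_postfilter(img, 4.5, g$pixel_size)
  expect_lt(abs(sum(f) - 1), 1e-6)
  # measured FWHM from a Gaussian fit to the impulse response
  v <- f[, 96]
  sigma_px <- sqrt(1 / (2 * log(v[96] / v[97])))
  fwhm <- 2.3548200450309493 * sigma_px * g$pixel_size
  expect_lt(abs(fwhm - 4.5) / 4.5, 0.02)
  # conservation on an extended object
  obj <- rasterize_phantom(make_uniform_cylinder(geometry = g), g)$activity
  expect_lt(abs(sum(gaussian_postfilter(obj, 4.5, g$pixel_size)) - sum(obj)) /
              sum(obj), 1e-6)
})

test_that("Poisson log-likelihood: oracle, stationarity and edge cases", {
  set.seed(10)
  y <- matrix(rpois(60, 4), 6, 10)
  ybar <- matrix(runif(60, 0.5, 8), 6, 10)
  ll <- poisson_loglik(y, ybar)
  oracle <- sum(dpois(y, ybar, log = TRUE)) + sum(lfactorial(y))
  expect_equal(ll, oracle, tolerance = 1e-12)
  # maximum at ybar = y against global rescaling
  expect_gt(poisson_loglik(y, y), poisson_loglik(y, y * 1.01))
  expect_gt(poisson_loglik(y, y), poisson_loglik(y, y * 0.99))
  # doubling ybar where y = 0 decreases the value
  y0 <- y; y0[] <- 0
  expect_gt(poisson_loglik(y0, ybar), poisson_loglik(y0, 2 * ybar))
  # impossible bins signalled as -Inf
  yb <- ybar; yb[1] <- 0; yy <- y; yy[1] <- 3
  expect_identical(poisson_loglik(yy, yb), -Inf)
})
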