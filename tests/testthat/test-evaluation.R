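test_that("SUV conversion follows the dose-per-weight definition", {
  expect_equal(suv_from_concentration(370000 / 70000, 370000, 70000), 1)
  expect_equal(suv_from_concentration(10, 370000, 70000),
               2 * suv_from_concentration(5, 370000, 70000))
  expect_equal(suv_from_concentration(5, 370000, 70000), 0.946, tolerance = 1e-3)
  expect_error(suv_from_concentration(5, 0, 70000), "dose")
  expect_error(suv_from_concentration(5, 370000, -1), "weight")
})

test_that("ROI statistics match a brute-force loop over mask pixels", {
  g <- small_geom()
  set.seed(21)
  img <- matrix(runif(g$grid_n^2, 0, 5), g$grid_n)
  mask <- region_mask_disk(g, 10, -20, 30)
  r <- roi("test", mask, "organ")
  st <- roi_stats(img, r)
  vals <- c()
  for (i in seq_len(g$grid_n)) for (j in seq_len(g$grid_n))
    if (mask[i, j]) vals <- c(vals, img[i, j])
  expect_identical(st$suv_mean, mean(vals))
  expect_identical(st$suv_max, max(vals))
  expect_gte(st$suv_max, st$suv_mean)
  # constant image and single hot pixel
  expect_equal(roi_stats(matrix(3, g$grid_n, g$grid_n), r)$suv_mean, 3)
  hot <- matrix(0, g$grid_n, g$grid_n)
  hot[which(mask)[1]] <- 7
  expect_equal(roi_stats(hot, r)$suv_max, 7)
  expect_equal(roi_stats(hot, r)$suv_mean, 7 / sum(mask))
  expect_error(roi("empty", matrix(FALSE, 4, 4)), "non-empty")
})

test_that("ROI statistics on the truth image reproduce assigned uniform values", {
  g <- pet_geometry()
  tr <- rasterize_phantom(make_torso_phantom(11, g), g)
  liver_i <- match("liver", tr$label_names)
  r <- roi("liver", tr$labels == liver_i, "organ")
  st <- roi_stats(tr$activity, r)
  expect_identical(st$suv_mean, 2.5)
  expect_identical(st$suv_max, 2.5)
})

test_that("percent SUV difference reproduces the worked clinical values", {
  expect_equal(suv_difference(3.78, 2.04), 85.29, tolerance = 1e-4)
  expect_equal(suv_difference(3.97, 4.06), 2.22, tolerance = 2e-3)
  expect_equal(suv_difference(5, 5), 0)
  expect_false(suv_difference(3.78, 2.04) == suv_difference(2.04, 3.78))
  expect_error(suv_difference(1, 0), "positive")
})

test_that("liver SUV variation reproduces the worked clinical values", {
  expect_equal(liver_suv_variation(2.90, 3.12), 7.05, tolerance = 1e-3)
  expect_equal(liver_suv_variation(1.37, 2.94), 53.40, tolerance = 1e-4)
  expect_equal(liver_suv_variation(2.5, 2.5), 0)
  expect_false(liver_suv_variation(2.9, 3.12) == liver_suv_variation(3.12, 2.9))
  expect_error(liver_suv_variation(1, 0), "positive")
})

test_that("40% delineation matches the analytic isocontour of a Gaussian blob", {
  g <- pet_geometry(grid_n = 64, pixel_size = 2, n_radial = 70,
                    radial_spacing = 2, fov_diameter = 128, n_angles = 4,
                    n_tof_bins = 3, tof_bin_width = 100)
  xc <- mlaapet:::pixel_centers(g)
  X <- matrix(xc, 64, 64)
  Y <- t(X)
  sb <- 10
  img <- exp(-((X - 3)^2 + (Y + 5)^2) / (2 * sb^2))
  region <- (X - 3)^2 + (Y + 5)^2 < 50^2
  m <- lesion_mask_40pct(img, region)
  r40 <- sb * sqrt(2 * log(1 / 0.4))
  equiv_radius <- sqrt(sum(m$mask) * g$pixel_size^2 / pi)
  expect_lt(abs(equiv_radius - r40), g$pixel_size)
})

test_that("40% delineation keeps a uniform region and drops disconnected blobs", {
  img <- matrix(0, 32, 32)
  img[10:15, 10:15] <- 2
  region <- matrix(FALSE, 32, 32)
  region[8:25, 8:25] <- TRUE
  m <- lesion_mask_40pct(img, region)
  expect_identical(m$mask, img >= 0.8 & region)
  # add a second, separated blob below threshold connectivity
  img2 <- img
  img2[22:24, 22:24] <- 1.5
  m2 <- lesion_mask_40pct(img2, region)
  expect_true(all(!m2$mask[22:24, 22:24]))
  expect_true(all(m2$mask[10:15, 10:15]))
  expect_error(lesion_mask_40pct(matrix(0, 32, 32), region), "positive")
})

test_that("SUV regression matches closed-form ordinary least squares", {
  r <- suv_regression(1:5, 1:5)
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  r2 <- suv_regression(1:5, 2 * (1:5) + 1)
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 1)
  expect_equal(r2$r_squared, 1)
  set.seed(31)
  x <- runif(20, 0, 10)
  y <- 1.2 * x + rnorm(20)
  f <- suv_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope_cf <- sxy / sxx
  intercept_cf <- mean(y) - slope_cf * mean(x)
  r2_cf <- (sxy / sqrt(sxx * sum((y - mean(y))^2)))^2
  expect_lt(abs(f$slope - slope_cf), 1e-10)
  expect_lt(abs(f$intercept - intercept_cf), 1e-10)
  expect_lt(abs(f$r_squared - r2_cf), 1e-12)
  expect_error(suv_regression(rep(1, 5), 1:5), "degenerate")
  expect_error(suv_regression(1:2, 1:2), "3 points")
})

test_that("identical reconstructions report zero differences and unit regression", {
  g <- pet_geometry()
  tr <- rasterize_phantom(make_torso_phantom(11, g), g)
  sim_truth <- c(tr, list(phantom = make_torso_phantom(11, g)))
  rois <- torso_rois(tr, g)
  fake <- list(activity = tr$activity + 0.01)  # strictly positive everywhere needed
  rep1 <- experiment_report(sim_truth, fake, fake, rois)
  expect_true(all(rep1$comparisons$diff_mean_pct == 0))
  expect_true(all(rep1$comparisons$diff_max_pct == 0))
  expect_true(all(abs(rep1$regressions$slope - 1) < 1e-12))
  expect_true(all(abs(rep1$regressions$r_squared - 1) < 1e-12))
  expect_equal(nrow(rep1$comparisons), length(rois))
  expect_equal(nrow(rep1$variations), 2)
})

test_that("lesion motion/non-motion groups partition the lesion set", {
  g <- pet_geometry()
  for (seed in c(7, 11, 19)) {
    tr <- rasterize_phantom(make_torso_phantom(seed, g), g)
    rois <- torso_rois(tr, g)
    lesion_names <- names(rois)[vapply(rois, function(r) r$tag, character(1)) == "lesion"]
    motion <- vapply(lesion_names, function(nm)
      mlaapet:::lesion_motion_affected(rois[[nm]], tr), logical(1))
    expect_equal(sum(motion) + sum(!motion), length(lesion_names))
    expect_true(motion[["lesion_dome"]])  # the dome lesion is motion-affected
  }
})

test_that("a single-count convergence curve equals the standalone reconstruction", {
  sim <- fx_small_noisy()
  g <- small_geom()
  roi_mask <- region_mask_disk(g, 0, 0, 40)
  ctl <- recon_control(n_subsets = 4, track_loglik = FALSE)
  curve <- convergence_curve(sim$data, sim$truth$mu, iterations = 3,
                             roi = roi_mask, control = ctl)
  standalone <- mlaa(sim$data, sim$truth$mu, ctl)
  expect_equal(curve$roi_mean, mean(standalone$activity[roi_mask]),
               tolerance = 1e-12)
})

test_that("the noiseless convergence curve approaches the truth", {
  sim <- fx_small_noiseless()
  g <- small_geom()
  roi_mask <- region_mask_disk(g, 0, 0, 40)
  ctl <- recon_control(n_subsets = 4, track_loglik = FALSE)
  curve <- convergence_curve(sim$data, sim$truth$mu, 1:5, roi_mask, ctl)
  err <- abs(curve$roi_mean - 2.0)
  expect_true(all(diff(err[2:5]) <= 1e-6))
  expect_lt(err[5], err[1])
})
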