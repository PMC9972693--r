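test_that("TOF timing resolution converts to spatial FWHM via c*dt/2", {
  expect_equal(tof_spatial_fwhm(418.5), 62.73, tolerance = 1e-4)
  expect_equal(tof_spatial_fwhm(0), 0)
  expect_equal(tof_spatial_fwhm(1000), 149.9, tolerance = 1e-3)
  expect_error(tof_spatial_fwhm(-1), ">= 0")
})

test_that("geometry invariants are enforced", {
  expect_error(pet_geometry(n_tof_bins = 12), "odd")
  expect_error(pet_geometry(n_radial = 10, radial_spacing = 3,
                            fov_diameter = 600), "radial extent")
  expect_error(pet_geometry(grid_n = 10, pixel_size = 3, fov_diameter = 600),
               "cover")
})

test_that("axis-aligned central LOR crosses pixels with full pixel-size chords", {
  g <- pet_geometry(n_radial = 9, n_angles = 4, radial_spacing = 3.15,
                    fov_diameter = 25, n_tof_bins = 3, tof_bin_width = 40,
                    tof_resolution_ps = 0, grid_n = 8, pixel_size = 3.15)
  p <- mlaapet:::cpp_trace_ray(g, 0, 0)  # vertical ray through the centre
  expect_equal(length(p$pixel), 8)
  expect_equal(p$length, rep(3.15, 8), tolerance = 1e-12)
})

test_that("an LOR with radial offset beyond the grid yields an empty path", {
  g <- tiny_geom()
  half_width <- g$grid_n * g$pixel_size / 2
  p <- mlaapet:::cpp_trace_ray(g, half_width + 1, 0)
  expect_length(p$pixel, 0)
})

test_that("diagonal chords match a supersampled line-integral oracle", {
  g <- pet_geometry(n_radial = 9, n_angles = 4, radial_spacing = 5,
                    fov_diameter = 40, n_tof_bins = 3, tof_bin_width = 40,
                    tof_resolution_ps = 0, grid_n = 8, pixel_size = 5)
  for (case in list(c(3.2, pi / 3.7), c(-6.1, pi / 7), c(0.4, 2.2))) {
    r <- case[1]; theta <- case[2]
    p <- mlaapet:::cpp_trace_ray(g, r, theta)
    w <- 8 * 5 / 2
    ns <- 4e4
    tt <- seq(-1.5 * w, 1.5 * w, length.out = ns)
    dt <- tt[2] - tt[1]
    x <- r * cos(theta) - tt * sin(theta)
    y <- r * sin(theta) + tt * cos(theta)
    ix <- floor((x + w) / 5)
    iy <- floor((y + w) / 5)
    ok <- ix >= 0 & ix < 8 & iy >= 0 & iy < 8
    oracle <- tapply(rep(dt, sum(ok)), ix[ok] + 8 * iy[ok] + 1, sum)
    lens <- setNames(p$length, p$pixel)
    all_pix <- union(names(oracle), names(lens))
    a <- ifelse(all_pix %in% names(lens), lens[all_pix], 0)
    b <- ifelse(all_pix %in% names(oracle), oracle[all_pix], 0)
    expect_lt(max(abs(a - b)) / max(b), 0.005)
  }
})

test_that("chord lengths per LOR sum to the geometric chord through the grid", {
  g <- tiny_geom()
  w <- g$grid_n * g$pixel_size / 2
  paths <- compute_ray_paths(g)
  for (p in paths) {
    if (length(p$pixel) == 0) next
    r <- (p$radial - (g$n_radial + 1) / 2) * g$radial_spacing
    theta <- (p$angle - 1) * pi / g$n_angles
    # independent chord: clip the line to the square [-w, w]^2
    d <- c(-sin(theta), cos(theta))
    o <- r * c(cos(theta), sin(theta))
    tmin <- -Inf; tmax <- Inf
    for (ax in 1:2) {
      if (abs(d[ax]) < 1e-14) next
      t1 <- (-w - o[ax]) / d[ax]; t2 <- (w - o[ax]) / d[ax]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
    expect_lt(abs(sum(p$length) - max(tmax - tmin, 0)), 1e-6)
  }
})

test_that("TOF bin weights match numeric quadrature of the Gaussian kernel", {
  g <- tiny_geom()
  sigma <- g$tof_sigma_mm
  for (pos in c(0, 7.3, -31.9, 55)) {
    w <- tof_weights(g, pos)
    edges <- (seq_len(g$n_tof_bins + 1) - 1 - g$n_tof_bins / 2) * g$tof_bin_width
    oracle <- vapply(seq_len(g$n_tof_bins), function(b)
      stats::integrate(function(t) dnorm(t, pos, sigma), edges[b], edges[b + 1],
                       rel.tol = 1e-12)$value, numeric(1))
    expect_lt(max(abs(w - oracle)), 1e-8)
    expect_true(all(w >= 0))
  }
})

test_that("TOF weights are symmetric at the centre and concentrate for wide bins", {
  g <- tiny_geom()
  w <- tof_weights(g, 0)
  expect_equal(w, rev(w))
  expect_gte(sum(tof_weights(g, 0)), 0.999)
  gw <- pet_geometry(n_radial = 24, n_angles = 12, radial_spacing = 3,
                     fov_diameter = 60, n_tof_bins = 3, tof_bin_width = 500,
                     tof_resolution_ps = 100, grid_n = 16, pixel_size = 4)
  w2 <- tof_weights(gw, 0)
  expect_gt(w2[2], 1 - 1e-10)
})

test_that("attenuation factors: unit at zero mu, analytic for a water disk, exponential", {
  g <- pet_geometry()
  zero <- matrix(0, g$grid_n, g$grid_n)
  expect_true(all(attenuation_factors(zero, g) == 1))

  # antialiased water disk (area-weighted rasterization) vs analytic chord
  n <- g$grid_n
  xc <- mlaapet:::pixel_centers(g)
  sub <- (seq_len(8) - 4.5) / 8 * g$pixel_size
  mu <- matrix(0, n, n)
  frac <- matrix(0, n, n)
  for (dx in sub) for (dy in sub)
    frac <- frac + (outer((xc + dx)^2, (xc + dy)^2, "+") <= 100^2)
  mu <- 0.096 * frac / 64
  af <- attenuation_factors(mu, g)
  central <- af[(g$n_radial / 2):(g$n_radial / 2 + 1), 1]
  r_off <- c(-0.5, 0.5) * g$radial_spacing
  expected <- exp(-0.096 * 2 * sqrt(100^2 - r_off^2) / 10)
  expect_lt(max(abs(central - expected) / expected), 0.005)

  # doubling mu squares every factor
  af2 <- attenuation_factors(2 * mu, g)
  expect_equal(af2, af^2, tolerance = 1e-10)
})
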