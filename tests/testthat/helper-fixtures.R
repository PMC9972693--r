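# shared geometries and memoised simulation/reconstruction fixtures

# small oracle geometry: TOF kernel fully contained in the binned range
# (grid diagonal/2 + 7 sigma < n_tof_bins * width / 2)
tiny_geom <- function() {
  pet_geometry(n_radial = 24, n_angles = 12, radial_spacing = 3,
               fov_diameter = 60, n_tof_bins = 9, tof_bin_width = 25,
               tof_resolution_ps = 150, grid_n = 16, pixel_size = 4)
}

# mid-size geometry for reconstruction behaviour tests (good TOF so the
# joint problem is well conditioned at this scale)
small_geom <- function() {
  pet_geometry(n_radial = 52, n_angles = 24, radial_spacing = 4,
               fov_diameter = 190, n_tof_bins = 13, tof_bin_width = 15,
               tof_resolution_ps = 100, grid_n = 48, pixel_size = 4)
}

small_cylinder <- function(concentration = 2.0) {
  phantom_spec(list(phantom_region("body", "disk", c(cx = 0, cy = 0, r = 60),
                                   concentration, 0.096)))
}

erode_mask <- function(m, k) {
  n <- nrow(m)
  p <- ncol(m)
  for (i in seq_len(k)) {
    mm <- m
    mm[-1, ] <- mm[-1, ] & m[-n, ]
    mm[-n, ] <- mm[-n, ] & m[-1, ]
    mm[, -1] <- mm[, -1] & m[, -p]
    mm[, -p] <- mm[, -p] & m[, -1]
    m <- mm
  }
  m
}

.fx_cache <- new.env(parent = emptyenv())
fx <- function(name, make) {
  if (!exists(name, envir = .fx_cache)) assign(name, make(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# small noiseless cylinder acquisition (fixed-point and recovery oracles)
fx_small_noiseless <- function() fx("small_noiseless", function() {
  simulate_acquisition(small_cylinder(), small_geom(), 5e5, 0.1,
                       seed = 3, noise = FALSE)
})

# small noisy cylinder acquisition (monotonicity, order-robustness)
fx_small_noisy <- function() fx("small_noisy", function() {
  simulate_acquisition(small_cylinder(), small_geom(), 2e5, 0.1, seed = 3)
})

# full-scale uniformity phantom study: 20 cm cylinder at 15.36 kBq/cc,
# 2e6 trues, scatter fraction 0.2
fx_phantom_study <- function() fx("phantom_study", function() {
  g <- pet_geometry()
  sim <- simulate_acquisition(make_uniform_cylinder(geometry = g), g,
                              2e6, 0.2, seed = 7)
  roi <- region_mask_disk(g, 0, 0, 75)
  list(geometry = g, sim = sim, roi = roi)
})

fx_phantom_recons <- function() fx("phantom_recons", function() {
  ps <- fx_phantom_study()
  ctl <- recon_control(track_loglik = FALSE)
  list(mlaa = mlaa(ps$sim$data, ps$sim$truth$mu, ctl, roi = ps$roi),
       osem = tof_osem(ps$sim$data, ps$sim$truth$mu, ctl, roi = ps$roi))
})

fx_phantom_convergence <- function() fx("phantom_convergence", function() {
  ps <- fx_phantom_study()
  convergence_curve(ps$sim$data, ps$sim$truth$mu, 1:7, ps$roi,
                    recon_control(track_loglik = FALSE))
})

# full-scale torso scenarios (matched / respiratory / metal), seed 11
fx_torso <- function(scenario) fx(paste0("torso_", scenario), function() {
  g <- pet_geometry()
  phantom <- make_torso_phantom(11, g)
  sim <- simulate_acquisition(phantom, g, 2e6, 0.2, seed = 11)
  spec <- switch(scenario,
                 matched = mismatch_spec("matched"),
                 respiratory = mismatch_spec("respiratory", shift_mm = 12),
                 metal = mismatch_spec("metal", inflation = 3))
  ct_mu <- corrupt_mu_map(sim$truth$mu, spec, g,
                          dome_rows = torso_dome_rows(sim$truth))
  ctl <- recon_control(track_loglik = FALSE)
  fit_o <- tof_osem(sim$data, ct_mu, ctl)
  fit_m <- mlaa(sim$data, ct_mu, ctl)
  rois <- torso_rois(sim$truth, g)
  if (scenario == "metal") {
    imp <- region_mask_disk(g, spec$implant$params["cx"],
                            spec$implant$params["cy"], spec$implant$params["r"])
    rois$implant_adjacent <- roi("implant_adjacent", dilate2(imp, 2L),
                                 "implant-adjacent")
  }
  report <- experiment_report(sim$truth, fit_m, fit_o, rois)
  list(geometry = g, sim = sim, ct_mu = ct_mu, mlaa = fit_m, osem = fit_o,
       rois = rois, report = report, spec = spec)
})

region_mask_disk <- function(geometry, cx, cy, r) {
  w <- geometry$grid_n * geometry$pixel_size / 2
  xc <- -w + (seq_len(geometry$grid_n) - 0.5) * geometry$pixel_size
  outer((xc - cx)^2, (xc - cy)^2, "+") <= r^2
}

dilate2 <- function(mask, k) {
  n <- nrow(mask)
  p <- ncol(mask)
  for (i in seq_len(k)) {
    g <- mask
    g[-1, ] <- g[-1, ] | mask[-n, ]
    g[-n, ] <- g[-n, ] | mask[-1, ]
    g[, -1] <- g[, -1] | mask[, -p]
    g[, -p] <- g[, -p] | mask[, -1]
    mask <- g
  }
  mask
}
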