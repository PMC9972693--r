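test_that("uniform cylinder rasterizes to the requested concentration and area", {
  g <- pet_geometry()
  ph <- make_uniform_cylinder(15.36, 200, g)
  tr <- rasterize_phantom(ph, g)
  disk <- tr$labels == 1
  expect_true(all(tr$activity[disk] == 15.36))
  expect_equal(mean(tr$activity[disk]), 15.36)
  expect_true(all(tr$mu[disk] == 0.096))
  expect_true(all(tr$activity[!disk] == 0))
  # rasterized area within one pixel-row of the analytic disk area
  area_px <- pi * 100^2 / g$pixel_size^2
  expect_lt(abs(sum(disk) - area_px), 2 * pi * 100 / g$pixel_size)
})

test_that("zero-concentration cylinder has empty activity but a mu disk", {
  g <- pet_geometry()
  tr <- rasterize_phantom(make_uniform_cylinder(0, 200, g), g)
  expect_true(all(tr$activity == 0))
  expect_gt(sum(tr$mu > 0), 0)
  expect_error(make_uniform_cylinder(15, 700, g), "field of view")
})

test_that("torso phantom is deterministic given the seed", {
  g <- pet_geometry()
  a <- rasterize_phantom(make_torso_phantom(5, g), g)
  b <- rasterize_phantom(make_torso_phantom(5, g), g)
  expect_identical(a, b)
  c <- rasterize_phantom(make_torso_phantom(6, g), g)
  expect_false(identical(a$activity, c$activity))
})

test_that("torso lesions keep at least 3x contrast over the liver", {
  g <- pet_geometry()
  for (seed in c(1, 11, 23)) {
    ph <- make_torso_phantom(seed, g)
    liver_act <- ph$regions[[match("liver", vapply(ph$regions, `[[`,
                                                   character(1), "label"))]]$activity
    lesion_acts <- vapply(ph$regions[grep("^lesion",
                                          vapply(ph$regions, `[[`, character(1), "label"))],
                          `[[`, numeric(1), "activity")
    expect_gte(length(lesion_acts), 2)
    expect_true(all(lesion_acts / liver_act >= 3))
  }
})

test_that("torso label map partitions the body support exactly", {
  g <- pet_geometry()
  tr <- rasterize_phantom(make_torso_phantom(11, g), g)
  body <- tr$mu > 0 | tr$activity > 0
  expect_true(all(tr$labels[body] > 0))
  expect_true(all(tr$labels[!body] == 0))
  # the label map records the topmost region: values match its assignment
  ph <- make_torso_phantom(11, g)
  for (i in seq_along(ph$regions)) {
    sel <- tr$labels == i
    if (!any(sel)) next
    expect_true(all(tr$activity[sel] == ph$regions[[i]]$activity))
    expect_true(all(tr$mu[sel] == ph$regions[[i]]$mu))
  }
})

test_that("matched corruption is the identity", {
  g <- pet_geometry()
  tr <- rasterize_phantom(make_torso_phantom(11, g), g)
  out <- corrupt_mu_map(tr$mu, mismatch_spec("matched"), g)
  expect_identical(out, tr$mu)
})

test_that("respiratory corruption shifts the dome band and conserves the rest", {
  g <- pet_geometry()
  tr <- rasterize_phantom(make_torso_phantom(11, g), g)
  rows <- torso_dome_rows(tr)
  out <- corrupt_mu_map(tr$mu, mismatch_spec("respiratory", shift_mm = 12), g,
                        dome_rows = rows)
  s <- round(12 / g$pixel_size)
  j_top <- max(rows)
  for (j in setdiff(rows, (j_top - s + 1):j_top))
    expect_equal(out[, j], tr$mu[, j + s])
  # vacated rows take lung attenuation inside the body
  vac <- (j_top - s + 1):j_top
  for (j in vac)
    expect_true(all(out[tr$mu[, j] > 0, j] %in% c(0.030, tr$mu[tr$mu[, j] > 0, j])))
  # untouched outside the band, hence the histogram there is conserved
  outside <- setdiff(seq_len(g$grid_n), rows)
  expect_identical(out[, outside], tr$mu[, outside])
  # a discontinuity exists at the band boundary
  expect_false(identical(out[, rows], tr$mu[, rows]))
})

test_that("metal corruption inflates the implant and leaves far tissue unchanged", {
  g <- pet_geometry()
  tr <- rasterize_phantom(make_torso_phantom(11, g), g)
  spec <- mismatch_spec("metal", inflation = 3)
  out <- corrupt_mu_map(tr$mu, spec, g)
  imp <- mlaapet:::region_mask(spec$implant, g)
  expect_equal(mean(out[imp]), 3 * mean(tr$mu[imp]), tolerance = 1e-12)
  xc <- mlaapet:::pixel_centers(g)
  d <- sqrt(outer((xc - spec$implant$params["cx"])^2,
                  (xc - spec$implant$params["cy"])^2, "+"))
  far <- d > 4 * spec$implant$params["r"]
  expect_identical(out[far], tr$mu[far])
  bad <- mismatch_spec("metal",
                       implant = phantom_region("implant", "disk",
                                                c(cx = 1e4, cy = 0, r = 5), 0, 0))
  expect_error(corrupt_mu_map(tr$mu, bad, g), "outside the grid")
})
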