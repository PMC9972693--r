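#' Geometric phantom specification
#'
#' A phantom is an ordered list of labelled geometric regions, each carrying a
#' tracer concentration (kBq/cc) and a 511 keV linear attenuation coefficient
#' (1/cm).  Later regions overwrite earlier ones when rasterized, so organs
#' are layered back-to-front.  Body weight and injected dose are carried for
#' SUV conversion.
#'
#' @param regions list of regions built with [phantom_region()].
#' @param body_weight_g body weight in grams (for SUV conversion).
#' @param injected_dose_kBq injected dose in kBq.
#' @return an object of class `phantom_spec`.
#' @seealso [make_uniform_cylinder()], [make_torso_phantom()],
#'   [rasterize_phantom()]
#' @export
phantom_spec <- function(regions, body_weight_g = NULL, injected_dose_kBq = NULL) {
  stopifnot(length(regions) >= 1)
  for (rg in regions) {
    stopifnot(inherits(rg, "phantom_region"))
    if (rg$activity < 0 || rg$mu < 0) stop("activities and mu must be >= 0")
  }
  structure(list(regions = regions, body_weight_g = body_weight_g,
                 injected_dose_kBq = injected_dose_kBq),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec with %d regions\n", length(x$regions)))
  for (rg in x$regions)
    cat(sprintf("  %-12s %-9s activity %6.2f kBq/cc  mu %.3f /cm\n",
                rg$label, rg$shape, rg$activity, rg$mu))
  invisible(x)
}

#' Single phantom region
#'
#' Shape primitives are `disk` (cx, cy, r), `ellipse` (cx, cy, rx, ry) and
#' `rect` (x0, x1, y0, y1), all in mm in scanner coordinates (origin on the
#' axis; the second image dimension is the cranio-caudal direction, +y
#' cranial).
#'
#' @param label region name (used as the ground-truth ROI label).
#' @param shape one of `"disk"`, `"ellipse"`, `"rect"`.
#' @param params named numeric vector of shape parameters (see above).
#' @param activity tracer concentration, kBq/cc.
#' @param mu linear attenuation at 511 keV, 1/cm.
#' @export
phantom_region <- function(label, shape = c("disk", "ellipse", "rect"),
                           params, activity, mu) {
  shape <- match.arg(shape)
  need <- switch(shape, disk = c("cx", "cy", "r"),
                 ellipse = c("cx", "cy", "rx", "ry"),
                 rect = c("x0", "x1", "y0", "y1"))
  if (!all(need %in% names(params)))
    stop(sprintf("shape '%s' needs parameters %s", shape, paste(need, collapse = ", ")))
  structure(list(label = label, shape = shape, params = params,
                 activity = activity, mu = mu),
            class = "phantom_region")
}

region_mask <- function(region, geometry) {
  xc <- pixel_centers(geometry)
  X <- matrix(xc, geometry$grid_n, geometry$grid_n)
  Y <- matrix(xc, geometry$grid_n, geometry$grid_n, byrow = TRUE)
  p <- region$params
  switch(region$shape,
         disk = (X - p["cx"])^2 + (Y - p["cy"])^2 <= p["r"]^2,
         ellipse = ((X - p["cx"]) / p["rx"])^2 + ((Y - p["cy"]) / p["ry"])^2 <= 1,
         rect = X >= p["x0"] & X <= p["x1"] & Y >= p["y0"] & Y <= p["y1"])
}

#' Rasterize a phantom onto the image grid
#'
#' Deterministic pixel-centre-in-shape rasterization (no antialiasing), so
#' region statistics on the truth images are exactly reproducible.  Regions
#' are painted in order; later regions overwrite earlier ones.
#'
#' @param phantom a [phantom_spec()].
#' @param geometry a [pet_geometry()].
#' @return list with `activity` and `mu` matrices and an integer `labels`
#'   matrix (0 = background, i = i-th region; the label map records the
#'   topmost region at each pixel).
#' @export
rasterize_phantom <- function(phantom, geometry) {
  stopifnot(inherits(phantom, "phantom_spec"))
  n <- geometry$grid_n
  activity <- matrix(0, n, n)
  mu <- matrix(0, n, n)
  labels <- matrix(0L, n, n)
  for (i in seq_along(phantom$regions)) {
    rg <- phantom$regions[[i]]
    m <- region_mask(rg, geometry)
    activity[m] <- rg$activity
    mu[m] <- rg$mu
    labels[m] <- i
  }
  list(activity = activity, mu = mu, labels = labels,
       label_names = vapply(phantom$regions, function(r) r$label, character(1)))
}

MU_WATER <- 0.096
MU_LUNG <- 0.030
MU_LIVER <- 0.098
MU_BONE <- 0.130

#' Uniform cylinder phantom
#'
#' A single water-attenuation disk (`mu` = 0.096/cm) of the given diameter at
#' the given tracer concentration, zero background — the standard uniformity
#' phantom used to calibrate the reconstruction parameters.
#'
#' @param concentration_kBq_cc fill concentration, kBq/cc (default 15.36, the
#'   clinically representative level used throughout the package examples).
#' @param diameter_mm cylinder diameter, mm (default 200).
#' @param geometry geometry whose FOV must contain the cylinder.
#' @return a [phantom_spec()].
#' @export
make_uniform_cylinder <- function(concentration_kBq_cc = 15.36,
                                  diameter_mm = 200,
                                  geometry = pet_geometry()) {
  stopifnot(concentration_kBq_cc >= 0)
  if (diameter_mm > geometry$fov_diameter)
    stop("cylinder diameter exceeds the field of view")
  phantom_spec(list(
    phantom_region("cylinder", "disk",
                   c(cx = 0, cy = 0, r = diameter_mm / 2),
                   activity = concentration_kBq_cc, mu = MU_WATER)))
}

#' Synthetic 2D torso phantom
#'
#' A deterministic-given-seed coronal torso slice: soft-tissue body ellipse
#' (activity 1.0 kBq/cc, mu 0.096), two lung fields (0.25, 0.030), liver
#' (2.5, 0.098), spine (1.5, 0.130) and 2-5 hot lesion disks (activity drawn
#' in 8-12, radius 6-10 mm), at least one inside the liver-dome band (top 25%
#' of liver rows) and at least one outside it.  Dose and weight default so
#' that the liver SUVmean is 2.5 (70 kg, 70 MBq).
#'
#' @param seed integer seed controlling lesion number and placement.
#' @param geometry a [pet_geometry()]; the body must fit the FOV.
#' @return a [phantom_spec()]; lesion regions are labelled
#'   `"lesion_dome"`, `"lesion_2"`, ...
#' @export
make_torso_phantom <- function(seed = 1L, geometry = pet_geometry()) {
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)

  body <- phantom_region("soft_tissue", "ellipse",
                         c(cx = 0, cy = 0, rx = 140, ry = 180),
                         activity = 1.0, mu = MU_WATER)
  lung_l <- phantom_region("lung_left", "ellipse",
                           c(cx = -72, cy = 80, rx = 46, ry = 82),
                           activity = 0.25, mu = MU_LUNG)
  lung_r <- phantom_region("lung_right", "ellipse",
                           c(cx = 72, cy = 80, rx = 46, ry = 82),
                           activity = 0.25, mu = MU_LUNG)
  liver <- phantom_region("liver", "ellipse",
                          c(cx = 62, cy = -48, rx = 68, ry = 58),
                          activity = 2.5, mu = MU_LIVER)
  spine <- phantom_region("spine", "rect",
                          c(x0 = -14, x1 = 14, y0 = -170, y1 = 170),
                          activity = 1.5, mu = MU_BONE)
  regions <- list(body, lung_l, lung_r, liver, spine)

  # liver-dome band: top 25% of liver rows (cranio-caudal = +y)
  liver_top <- -48 + 58
  liver_h <- 2 * 58
  dome_lo <- liver_top - 0.25 * liver_h

  n_lesions <- sample(2:5, 1)
  lesions <- list()
  placed <- matrix(numeric(0), ncol = 3)  # cx, cy, r
  try_place <- function(cx_rng, cy_rng, inside_fun) {
    for (i in 1:200) {
      cx <- stats::runif(1, cx_rng[1], cx_rng[2])
      cy <- stats::runif(1, cy_rng[1], cy_rng[2])
      r <- stats::runif(1, 6, 10)
      if (!inside_fun(cx, cy, r)) next
      if (nrow(placed) > 0 &&
          any(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) < placed[, 3] + r + 6))
        next
      return(c(cx, cy, r))
    }
    stop("failed to place a lesion")
  }
  in_liver <- function(cx, cy, r)
    ((cx - 62) / (68 - r))^2 + ((cy + 48) / (58 - r))^2 <= 1
  in_dome <- function(cx, cy, r) in_liver(cx, cy, r) && (cy - r) >= dome_lo
  in_body_soft <- function(cx, cy, r) {
    (cx / (140 - r - 4))^2 + (cy / (180 - r - 4))^2 <= 1 &&
      abs(cx) > 14 + r + 4 &&                       # off the spine
      !(((cx - 62) / (68 + r))^2 + ((cy + 48) / (58 + r))^2 <= 1) &&  # off the liver
      !(((cx + 72) / (46 + r))^2 + ((cy - 80) / (82 + r))^2 <= 1) &&  # off the lungs
      !(((cx - 72) / (46 + r))^2 + ((cy - 80) / (82 + r))^2 <= 1)
  }

  # one lesion in the liver dome band, one clearly outside it, rest anywhere soft
  p <- try_place(c(20, 110), c(dome_lo, liver_top), in_dome)
  placed <- rbind(placed, p)
  lesions[[1]] <- phantom_region("lesion_dome", "disk",
                                 c(cx = p[1], cy = p[2], r = p[3]),
                                 activity = stats::runif(1, 8, 12), mu = MU_WATER)
  for (i in 2:n_lesions) {
    p <- try_place(c(-130, 130), c(-170, 40), in_body_soft)
    placed <- rbind(placed, p)
    lesions[[i]] <- phantom_region(paste0("lesion_", i), "disk",
                                   c(cx = p[1], cy = p[2], r = p[3]),
                                   activity = stats::runif(1, 8, 12), mu = MU_WATER)
  }

  phantom_spec(c(regions, lesions),
               body_weight_g = 70000, injected_dose_kBq = 70000)
}

#' Attenuation-map mismatch specification
#'
#' Describes how the "CT" attenuation map handed to the reconstruction
#' differs from the truth: `matched` (identical), `respiratory` (a horizontal
#' band containing the liver dome translated caudally by `shift_mm`, vacated
#' pixels taking lung attenuation — the classic free-breathing CT/PET
#' mismatch) or `metal` (an implant region with inflated attenuation plus
#' alternating streak ripples along rays through it).
#'
#' @param mode one of `"matched"`, `"respiratory"`, `"metal"`.
#' @param shift_mm cranio-caudal dome shift, mm (respiratory; >= 0).
#' @param implant a [phantom_region()]-style shape for the implant (metal).
#' @param inflation multiplicative mu inflation inside the implant (>= 1).
#' @param streak_amplitude relative amplitude of the alternating streak
#'   ripples around the implant (metal), as a fraction of water mu.
#' @export
mismatch_spec <- function(mode = c("matched", "respiratory", "metal"),
                          shift_mm = 12, implant = NULL, inflation = 3,
                          streak_amplitude = 0.15) {
  mode <- match.arg(mode)
  stopifnot(shift_mm >= 0, inflation >= 1)
  if (mode == "metal" && is.null(implant))
    implant <- phantom_region("implant", "disk", c(cx = -60, cy = -30, r = 11),
                              activity = 0, mu = 0)
  structure(list(mode = mode, shift_mm = shift_mm, implant = implant,
                 inflation = inflation, streak_amplitude = streak_amplitude),
            class = "mismatch_spec")
}

#' Corrupt an attenuation map
#'
#' Applies a [mismatch_spec()] to a true attenuation image to produce the
#' "CT" map used for attenuation correction.  `matched` returns an identical
#' copy; `respiratory` translates the horizontal band containing the liver
#' dome caudally by `shift_mm` (vacated rows take lung attenuation), leaving
#' everything outside the band untouched; `metal` multiplies mu inside the
#' implant region by the inflation factor and adds alternating streak
#' ripples along rays through the implant centre, clipped at 0.
#'
#' @param true_mu `grid_n x grid_n` true attenuation image (1/cm).
#' @param spec a [mismatch_spec()].
#' @param geometry a [pet_geometry()].
#' @param dome_rows optional integer rows (second-index values) of the
#'   liver-dome band; required for respiratory mode (see
#'   [torso_dome_rows()]).
#' @return corrupted attenuation matrix.
#' @export
corrupt_mu_map <- function(true_mu, spec, geometry, dome_rows = NULL) {
  stopifnot(inherits(spec, "mismatch_spec"))
  check_image(true_mu, geometry, "true_mu")
  if (spec$mode == "matched") return(true_mu)
  if (spec$mode == "respiratory") {
    if (is.null(dome_rows)) stop("respiratory corruption needs dome_rows")
    s <- max(1L, as.integer(round(spec$shift_mm / geometry$pixel_size)))
    j_top <- max(dome_rows)
    j_lo <- min(dome_rows)
    out <- true_mu
    for (j in j_lo:j_top) {
      src <- j + s
      if (src <= j_top) out[, j] <- true_mu[, src]
      else out[, j][true_mu[, j] > 0] <- MU_LUNG
    }
    return(out)
  }
  # metal
  m <- region_mask(spec$implant, geometry)
  if (!any(m)) stop("implant region lies outside the grid")
  out <- true_mu
  out[m] <- out[m] * spec$inflation
  if (spec$streak_amplitude > 0) {
    xc <- pixel_centers(geometry)
    X <- matrix(xc, geometry$grid_n, geometry$grid_n)
    Y <- matrix(xc, geometry$grid_n, geometry$grid_n, byrow = TRUE)
    p <- spec$implant$params
    ang <- atan2(Y - p["cy"], X - p["cx"])
    d <- sqrt((X - p["cx"])^2 + (Y - p["cy"])^2)
    ring <- !m & d <= 3.5 * p["r"] & true_mu > 0
    ripple <- spec$streak_amplitude * MU_WATER * sign(sin(8 * ang[ring]))
    out[ring] <- pmax(0, out[ring] + ripple)
  }
  out
}

#' Liver-dome band rows of a rasterized torso
#'
#' The dome band is defined as the top 25% of rows (second image index,
#' cranio-caudal) occupied by the liver label.
#'
#' @param truth a [rasterize_phantom()] result for a torso phantom.
#' @return integer vector of row indices.
#' @export
torso_dome_rows <- function(truth) {
  liver_idx <- match("liver", truth$label_names)
  if (is.na(liver_idx)) stop("phantom has no liver region")
  rows <- which(apply(truth$labels == liver_idx, 2, any))
  h <- length(rows)
  rows[rows > max(rows) - ceiling(0.25 * h)]
}

# save/restore RNG state around seeded simulation
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
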