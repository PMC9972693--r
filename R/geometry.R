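#' 2D TOF-PET scanner geometry
#'
#' Defines the ring geometry, sinogram binning, TOF binning and reconstruction
#' grid shared by every projector and reconstruction in the package.  An LOR
#' is indexed by (radial bin, angle); the signed radial offset of radial bin
#' `i` (1-based) is `(i - (n_radial + 1) / 2) * radial_spacing` mm and angle
#' `k` is `(k - 1) * pi / n_angles`.  The TOF coordinate is measured along the
#' LOR with 0 at the closest approach to the scanner axis; `n_tof_bins` is odd
#' so a centred bin exists.
#'
#' The defaults reproduce a clinical whole-body TOF scanner at single-slice
#' scale: a 192 x 192 image matrix with 3.15 mm pixels, 192 radial bins at
#' 3.15 mm, 100 azimuthal angles over 180 degrees, 13 TOF bins of 30 mm and a
#' 418.5 ps coincidence timing resolution (62.73 mm spatial FWHM along the
#' LOR, so the 30 mm TOF bin width is well below the TOF kernel width).
#'
#' @param n_radial number of radial bins.
#' @param n_angles number of projection angles over 180 degrees.
#' @param radial_spacing radial bin spacing, mm.
#' @param fov_diameter reconstructed field-of-view diameter, mm.
#' @param n_tof_bins odd number of TOF bins.
#' @param tof_bin_width TOF bin width along the LOR, mm.
#' @param tof_resolution_ps coincidence timing resolution FWHM, picoseconds.
#' @param grid_n image matrix side.
#' @param pixel_size image pixel size, mm.
#' @return an object of class `pet_geometry`.
#' @examples
#' geom <- pet_geometry()
#' geom
#' @export
pet_geometry <- function(n_radial = 192L, n_angles = 100L,
                         radial_spacing = 3.15, fov_diameter = 600,
                         n_tof_bins = 13L, tof_bin_width = 30,
                         tof_resolution_ps = 418.5,
                         grid_n = 192L, pixel_size = 3.15) {
  n_radial <- as.integer(n_radial)
  n_angles <- as.integer(n_angles)
  n_tof_bins <- as.integer(n_tof_bins)
  grid_n <- as.integer(grid_n)
  stopifnot(n_radial >= 1L, n_angles >= 1L, grid_n >= 1L,
            radial_spacing > 0, pixel_size > 0, tof_bin_width > 0,
            tof_resolution_ps >= 0)
  if (n_tof_bins %% 2L == 0L)
    stop("n_tof_bins must be odd so that a centred TOF bin exists")
  if (fov_diameter > n_radial * radial_spacing + 1e-9)
    stop("fov_diameter exceeds the radial extent n_radial * radial_spacing")
  if (grid_n * pixel_size < fov_diameter - 1e-9)
    stop("image grid (grid_n * pixel_size) does not cover fov_diameter")
  g <- list(n_radial = n_radial, n_angles = n_angles,
            radial_spacing = radial_spacing, fov_diameter = fov_diameter,
            n_tof_bins = n_tof_bins, tof_bin_width = tof_bin_width,
            tof_resolution_ps = tof_resolution_ps,
            grid_n = grid_n, pixel_size = pixel_size,
            tof_sigma_mm = tof_spatial_fwhm(tof_resolution_ps) / 2.3548200450309493)
  class(g) <- "pet_geometry"
  g
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat("2D TOF-PET geometry\n")
  cat(sprintf("  sinogram : %d radial x %d angles x %d TOF bins (%.2f mm radial, %.0f mm TOF)\n",
              x$n_radial, x$n_angles, x$n_tof_bins, x$radial_spacing, x$tof_bin_width))
  cat(sprintf("  TOF      : %.1f ps FWHM (%.2f mm along the LOR)\n",
              x$tof_resolution_ps, tof_spatial_fwhm(x$tof_resolution_ps)))
  cat(sprintf("  image    : %d x %d pixels of %.2f mm, FOV %.0f mm\n",
              x$grid_n, x$grid_n, x$pixel_size, x$fov_diameter))
  invisible(x)
}

#' Spatial TOF localization FWHM
#'
#' Converts a coincidence timing resolution to the spatial full width at half
#' maximum of the emission-point localization along the LOR,
#' `FWHM_x = c * dt / 2` with `c` the speed of light.
#'
#' @param tof_resolution_ps timing FWHM in picoseconds (non-negative).
#' @return spatial FWHM in mm; 418.5 ps gives 62.73 mm.
#' @export
tof_spatial_fwhm <- function(tof_resolution_ps) {
  if (any(tof_resolution_ps < 0)) stop("tof_resolution_ps must be >= 0")
  c_mm_per_ns <- 299.792458
  c_mm_per_ns * tof_resolution_ps / 1000 / 2
}

# pixel-centre coordinates of the grid (mm, origin at the scanner axis)
pixel_centers <- function(geometry) {
  W <- geometry$grid_n * geometry$pixel_size / 2
  -W + (seq_len(geometry$grid_n) - 0.5) * geometry$pixel_size
}

# boolean mask of the circular field of view on the grid
fov_mask <- function(geometry, diameter = geometry$fov_diameter) {
  xc <- pixel_centers(geometry)
  outer(xc^2, xc^2, "+") <= (diameter / 2)^2
}

# voxel volume in cc (slice thickness taken equal to the pixel size)
voxel_cc <- function(geometry) {
  geometry$pixel_size^3 / 1000
}

#' TOF bin weights for an emission position
#'
#' Integrals of the Gaussian TOF localization kernel (FWHM from
#' [tof_spatial_fwhm()]) centred at a position along the LOR over each TOF
#' bin, i.e. differences of the Gaussian CDF at the bin edges.  Weights sum to
#' at most 1; mass falling outside the binned TOF range is lost.
#'
#' @param geometry a [pet_geometry()].
#' @param along_ray_position emission position along the LOR, mm (0 at the
#'   closest approach to the scanner axis).
#' @return numeric vector of length `n_tof_bins`.
#' @export
tof_weights <- function(geometry, along_ray_position) {
  nt <- geometry$n_tof_bins
  edges <- (seq_len(nt + 1) - 1 - nt / 2) * geometry$tof_bin_width
  s <- geometry$tof_sigma_mm
  if (s <= 0) {
    w <- numeric(nt)
    b <- floor((along_ray_position - edges[1]) / geometry$tof_bin_width) + 1
    if (b >= 1 && b <= nt) w[b] <- 1
    return(w)
  }
  diff(stats::pnorm(edges, mean = along_ray_position, sd = s))
}

#' Exact pixel intersections of every LOR
#'
#' Traces every (radial, angle) LOR through the image grid with a Siddon-type
#' exact traversal.  For each LOR the crossed pixels, chord lengths and
#' along-ray segment midpoints are returned; an LOR missing the grid yields an
#' empty path.  Intended for inspection and testing at small grid sizes — the
#' projectors retrace rays internally in compiled code.
#'
#' @param geometry a [pet_geometry()].
#' @return a list of length `n_radial * n_angles` (radial index fastest); each
#'   element has `pixel` (1-based column-major index), `length` (mm), `tmid`
#'   (mm along the LOR), `radial` and `angle` indices.
#' @export
compute_ray_paths <- function(geometry) {
  stopifnot(inherits(geometry, "pet_geometry"))
  out <- vector("list", geometry$n_radial * geometry$n_angles)
  idx <- 1L
  for (ka in seq_len(geometry$n_angles)) {
    theta <- (ka - 1) * pi / geometry$n_angles
    for (ir in seq_len(geometry$n_radial)) {
      r <- (ir - (geometry$n_radial + 1) / 2) * geometry$radial_spacing
      p <- cpp_trace_ray(geometry, r, theta)
      p$radial <- ir
      p$angle <- ka
      out[[idx]] <- p
      idx <- idx + 1L
    }
  }
  out
}

check_image <- function(img, geometry, what = "image") {
  if (!is.matrix(img) || nrow(img) != geometry$grid_n || ncol(img) != geometry$grid_n)
    stop(sprintf("%s must be a %d x %d matrix", what, geometry$grid_n, geometry$grid_n))
  invisible(img)
}

all_angles <- function(geometry) seq_len(geometry$n_angles)

#' Per-LOR attenuation factors
#'
#' `exp(-integral of mu along the LOR)` for every LOR, with `mu` in 1/cm and
#' chord lengths in mm (converted internally).  Factors lie in (0, 1] and are
#' monotone non-increasing in every `mu` value.
#'
#' @param mu `grid_n x grid_n` matrix of 511 keV linear attenuation
#'   coefficients, 1/cm.
#' @param geometry a [pet_geometry()].
#' @param angles optional 1-based angle subset (default all).
#' @return `n_radial x length(angles)` matrix of factors.
#' @export
attenuation_factors <- function(mu, geometry, angles = all_angles(geometry)) {
  check_image(mu, geometry, "mu")
  exp(-cpp_fp_line(geometry, mu, as.integer(angles)) / 10)
}

#' Attenuated TOF forward projection
#'
#' Expected TOF sinogram of an activity image under the Poisson mean model
#' `ybar(r, theta, t) = calib * a(r, theta) * sum_j l_j w_j(t) lambda_j +
#' additive`, with `a` the attenuation factors of `mu`, `l_j` exact pixel
#' chord lengths (mm) and `w_j(t)` Gaussian TOF bin weights.  Linear in the
#' activity at fixed `mu`.
#'
#' @param activity `grid_n x grid_n` activity image (kBq/cc).
#' @param mu attenuation image (1/cm), or `NULL` for no attenuation.
#' @param geometry a [pet_geometry()].
#' @param additive additive (scatter) expectation, same shape as the output,
#'   or a scalar.
#' @param calib calibration factor mapping line integrals to expected counts.
#' @param angles optional 1-based angle subset.
#' @return array `n_radial x length(angles) x n_tof_bins`.
#' @export
forward_project <- function(activity, mu = NULL, geometry,
                            additive = 0, calib = 1,
                            angles = all_angles(geometry)) {
  check_image(activity, geometry, "activity")
  angles <- as.integer(angles)
  y <- cpp_fp_tof(geometry, activity, angles)
  if (!is.null(mu)) {
    a <- attenuation_factors(mu, geometry, angles)
    y <- y * as.vector(a)  # recycled over the TOF dimension
  }
  y <- y * calib
  if (!identical(additive, 0)) {
    if (length(additive) != 1 && !all(dim(additive) == dim(y)))
      stop("additive term shape does not match the projection")
    y <- y + additive
  }
  y
}

#' Attenuated TOF backprojection (adjoint of [forward_project()])
#'
#' Exact adjoint of the attenuated TOF forward operator without the additive
#' term: `sum_i calib * a_i * l_ij * w_ijt * values_i,t` accumulated per
#' pixel.
#'
#' @param values sinogram-shaped array (`n_radial x length(angles) x
#'   n_tof_bins`).
#' @inheritParams forward_project
#' @return `grid_n x grid_n` matrix.
#' @export
back_project <- function(values, mu = NULL, geometry, calib = 1,
                         angles = all_angles(geometry)) {
  angles <- as.integer(angles)
  dims <- c(geometry$n_radial, length(angles), geometry$n_tof_bins)
  if (is.null(dim(values)) || !all(dim(values) == dims))
    stop("values must be an n_radial x n_angles x n_tof_bins array")
  v <- values
  if (!is.null(mu)) {
    a <- attenuation_factors(mu, geometry, angles)
    v <- v * as.vector(a)
  }
  cpp_bp_tof(geometry, as.vector(v) * calib, angles)
}
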