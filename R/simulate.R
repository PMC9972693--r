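#' TOF sinogram container
#'
#' Measured (or expected) counts indexed (radial, angle, TOF bin) together
#' with the known additive background (scatter) expectation and the
#' calibration factor mapping kBq/cc line integrals to expected counts.
#'
#' @param counts non-negative `n_radial x n_angles x n_tof_bins` array.
#' @param additive same-shape non-negative expected background term.
#' @param calib unitless duration/sensitivity calibration factor.
#' @param geometry the [pet_geometry()] the shapes refer to.
#' @export
tof_sinogram <- function(counts, additive = NULL, calib = 1, geometry) {
  dims <- c(geometry$n_radial, geometry$n_angles, geometry$n_tof_bins)
  if (is.null(dim(counts)) || !all(dim(counts) == dims))
    stop("counts shape does not match the geometry")
  if (is.null(additive)) additive <- array(0, dims)
  if (!all(dim(additive) == dims))
    stop("additive shape does not match the geometry")
  if (any(counts < 0) || any(additive < 0))
    stop("counts and additive must be non-negative")
  storage.mode(counts) <- "double"
  storage.mode(additive) <- "double"
  structure(list(counts = counts, additive = additive, calib = calib,
                 geometry = geometry),
            class = "tof_sinogram")
}

#' @export
print.tof_sinogram <- function(x, ...) {
  cat(sprintf("TOF sinogram %d x %d x %d: %.3g counts (additive expectation %.3g), calib %.4g\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$counts), sum(x$additive), x$calib))
  invisible(x)
}

# separable Gaussian smoothing of an array along one dimension (zero-padded,
# kernel normalized to unit sum)
smooth_dim <- function(arr, dim_i, sigma) {
  if (sigma <= 0) return(arr)
  n <- dim(arr)[dim_i]
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + r + 1]
  }
  m <- apply(arr, setdiff(seq_along(dim(arr)), dim_i), function(v) K %*% v)
  aperm(array(m, dim(arr)[c(dim_i, setdiff(seq_along(dim(arr)), dim_i))]),
        order(c(dim_i, setdiff(seq_along(dim(arr)), dim_i))))
}

#' Simulate a Poisson TOF acquisition of a phantom
#'
#' Rasterizes the phantom, forms the expected trues via the attenuated TOF
#' forward model with the true attenuation map, scales the calibration so the
#' expected trues sum equals `expected_true_counts`, builds the additive
#' (scatter) expectation as a heavily smoothed copy of the trues scaled to
#' the requested scatter fraction `additive / (additive + trues)`, and draws
#' Poisson counts.  The additive term is returned exactly as used, so the
#' reconstruction sees the same known background that generated the data —
#' mirroring a pre-computed scatter estimate supplied to the reconstructor.
#'
#' @param phantom a [phantom_spec()].
#' @param geometry a [pet_geometry()].
#' @param expected_true_counts expected total true counts (> 0).
#' @param scatter_fraction scatter-to-total fraction in `[0, 1)`.
#' @param seed integer seed for the Poisson draw.
#' @param noise draw Poisson counts (default); `FALSE` returns the exact
#'   expectation as counts (noiseless data for convergence studies).
#' @return list with `data` (a [tof_sinogram()]) and `truth` (activity, mu,
#'   labels, label_names, phantom).
#' @export
simulate_acquisition <- function(phantom, geometry = pet_geometry(),
                                 expected_true_counts = 2e6,
                                 scatter_fraction = 0.2,
                                 seed = 1L, noise = TRUE) {
  stopifnot(expected_true_counts > 0,
            scatter_fraction >= 0, scatter_fraction < 1)
  truth <- rasterize_phantom(phantom, geometry)
  shape <- forward_project(truth$activity, truth$mu, geometry)
  tot <- sum(shape)
  if (tot > 0) {
    calib <- expected_true_counts / tot
    trues <- shape * calib
  } else {
    calib <- 1
    trues <- shape
  }
  if (scatter_fraction > 0 && sum(trues) > 0) {
    add <- smooth_dim(trues, 1L, 12)
    add <- smooth_dim(add, 3L, 1.5)
    add <- smooth_dim(add, 2L, 4)
    add <- add * (scatter_fraction / (1 - scatter_fraction)) * sum(trues) / sum(add)
  } else {
    add <- array(0, dim(trues))
  }
  ybar <- trues + add
  if (noise) {
    rs <- local_rng(seed)
    on.exit(rs(), add = TRUE)
    counts <- array(rpois(length(ybar), ybar), dim(ybar))
  } else {
    counts <- ybar
  }
  list(data = tof_sinogram(counts, add, calib, geometry),
       truth = c(truth, list(phantom = phantom)))
}
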