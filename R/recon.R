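#' Reconstruction control parameters
#'
#' Settings shared by [tof_osem()] and [mlaa()].  The defaults are the
#' clinical protocol used throughout the package: 3 iterations of 10 ordered
#' subsets with a 4.5 mm FWHM Gaussian post-filter.  All reconstructions are
#' deterministic — there is no internal randomness.
#'
#' @param n_iterations number of full iterations (>= 1).
#' @param n_subsets number of ordered subsets; must divide `n_angles`.
#' @param postfilter_fwhm_mm Gaussian post-filter FWHM, mm (0 disables).
#' @param total_activity_prior total-activity scale constraint in kBq (MLAA
#'   only); `NULL` means compute it from a reference OSEM reconstruction via
#'   [compute_total_activity_prior()].
#' @param exclusion_thresholds `(low, high)` attenuation thresholds (1/cm)
#'   for [exclusion_mask_from_mu()]; pixels below `low` inside the body or
#'   above `high` are excluded from the scale prior and frozen in MLTR.
#' @param interleave `"per-subset"` (one MLEM then one MLTR sub-update per
#'   subset) or `"per-iteration"` (a full MLEM sweep then a full MLTR sweep).
#' @param mltr_relaxation step damping factor for the MLTR update.
#' @param mu_init uniform attenuation initialization inside the estimation
#'   support, 1/cm.
#' @param mu_cap upper clip for attenuation estimates, 1/cm.
#' @param support_threshold relative threshold (fraction of each angle's
#'   maximum scatter-corrected projection value) used by the sinogram-strip
#'   estimate of the MLAA estimation support; see [mlaa()] and
#'   [estimate_support()].
#' @param keep_iterations store the activity image after every iteration
#'   (used by [convergence_curve()]).
#' @param track_loglik record the Poisson log-likelihood per iteration.
#' @return an object of class `recon_control`.
#' @export
recon_control <- function(n_iterations = 3L, n_subsets = 10L,
                          postfilter_fwhm_mm = 4.5,
                          total_activity_prior = NULL,
                          exclusion_thresholds = c(0.02, 0.18),
                          interleave = c("per-subset", "per-iteration"),
                          mltr_relaxation = 1,
                          mu_init = 0.096, mu_cap = 0.5,
                          support_threshold = 0.05,
                          keep_iterations = FALSE,
                          track_loglik = TRUE) {
  interleave <- match.arg(interleave)
  stopifnot(n_iterations >= 1, n_subsets >= 1, postfilter_fwhm_mm >= 0,
            length(exclusion_thresholds) == 2,
            exclusion_thresholds[1] < exclusion_thresholds[2],
            mltr_relaxation > 0, mu_cap > 0,
            support_threshold > 0, support_threshold < 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 postfilter_fwhm_mm = postfilter_fwhm_mm,
                 total_activity_prior = total_activity_prior,
                 exclusion_thresholds = exclusion_thresholds,
                 interleave = interleave,
                 mltr_relaxation = mltr_relaxation,
                 mu_init = mu_init, mu_cap = mu_cap,
                 support_threshold = support_threshold,
                 keep_iterations = keep_iterations,
                 track_loglik = track_loglik),
            class = "recon_control")
}

subset_angles <- function(geometry, n_subsets, s) {
  seq.int(s, geometry$n_angles, by = n_subsets)
}

check_subsets <- function(geometry, n_subsets) {
  if (geometry$n_angles %% n_subsets != 0L)
    stop(sprintf("n_subsets (%d) must divide n_angles (%d)",
                 n_subsets, geometry$n_angles))
}

#' Poisson log-likelihood (constant terms dropped)
#'
#' `sum(y * log(ybar) - ybar)` over all sinogram bins, with the convention
#' `0 * log(0) = 0`.  A bin with `ybar = 0` and `y > 0` has likelihood zero,
#' signalled explicitly as `-Inf`.
#'
#' @param data observed counts (array or [tof_sinogram()]).
#' @param expected expected counts, same shape.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(data, expected) {
  y <- if (inherits(data, "tof_sinogram")) data$counts else data
  if (any(y < 0)) stop("negative counts")
  if (any(expected < 0)) stop("negative expectation")
  bad <- expected == 0 & y > 0
  if (any(bad)) return(-Inf)
  pos <- y > 0
  sum(y[pos] * log(expected[pos])) - sum(expected)
}

#' Gaussian post-filter
#'
#' Separable isotropic Gaussian convolution with `sigma = fwhm / 2.3548`
#' converted to pixels; the discrete kernel (truncated at 6 sigma) is
#' normalized to unit sum so the image total is conserved for objects away
#' from the grid boundary.
#'
#' @param image `grid_n x grid_n` matrix.
#' @param fwhm_mm filter FWHM in mm; 0 returns the image unchanged.
#' @param pixel_size pixel size in mm.
#' @return filtered matrix.
#' @export
gaussian_postfilter <- function(image, fwhm_mm, pixel_size) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(image)
  sigma <- fwhm_mm / 2.3548200450309493 / pixel_size
  n <- nrow(image)
  r <- max(1L, ceiling(6 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + r + 1]
  }
  K %*% image %*% t(K)
}

#' Exclusion mask from a reference attenuation map
#'
#' Marks pixels whose reference (CT-derived) attenuation is suspicious:
#' below `low` while inside the filled body support (air pockets and
#' lung-boundary zones, where respiratory mismatch concentrates) or above
#' `high` anywhere (dense implants).  The mask is used both to exclude
#' pixels from the total-activity scale prior and as the frozen-pixel mask
#' for the MLTR attenuation update.
#'
#' @param reference_mu reference attenuation matrix, 1/cm.
#' @param thresholds `(low, high)` in 1/cm, `low < high`.
#' @return logical matrix.
#' @export
exclusion_mask_from_mu <- function(reference_mu, thresholds = c(0.02, 0.18)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  body <- fill_holes(reference_mu >= thresholds[1])
  (body & reference_mu < thresholds[1]) | reference_mu > thresholds[2]
}

#' Estimate the object support from TOF emission data
#'
#' Visible-hull support estimate used to initialize the MLAA joint
#' estimation: the additive (scatter) expectation is subtracted from the
#' TOF-summed projections, each angle's radial profile is lightly smoothed
#' and thresholded at a fraction of its maximum, and a pixel belongs to the
#' support when essentially every ray through it lies inside the thresholded
#' strips.  Robust to hot lesions and to the interior suppression of
#' non-attenuation-corrected images, at the cost of convexifying concave
#' body outlines.
#'
#' @param data a [tof_sinogram()].
#' @param threshold fraction of the per-angle maximum (default 0.05).
#' @return logical `grid_n x grid_n` support mask.
#' @export
estimate_support <- function(data, threshold = 0.05) {
  stopifnot(inherits(data, "tof_sinogram"))
  geometry <- data$geometry
  ang <- all_angles(geometry)
  ynt <- apply(data$counts, c(1, 2), sum) - apply(data$additive, c(1, 2), sum)
  ynt <- pmax(ynt, 0)
  ynt <- apply(ynt, 2, function(v) {
    f <- stats::filter(v, rep(1 / 5, 5), sides = 2)
    f[is.na(f)] <- 0
    f
  })
  mx <- apply(ynt, 2, max)
  if (all(mx == 0)) return(fov_mask(geometry))
  strip <- sweep(ynt, 2, pmax(mx, .Machine$double.xmin), "/") > threshold
  inside <- cpp_bp_line(geometry, strip + 0, ang)
  total <- cpp_bp_line(geometry, matrix(1, geometry$n_radial,
                                        geometry$n_angles), ang)
  (inside / pmax(total, 1e-12)) >= 0.999
}

# fill holes of a logical mask: complement components touching the border stay
# background, everything else becomes foreground (vectorized frontier BFS)
fill_holes <- function(mask) {
  n <- nrow(mask)
  m <- ncol(mask)
  outside <- matrix(FALSE, n, m)
  frontier <- !mask
  frontier[2:(n - 1), 2:(m - 1)] <- FALSE
  outside <- frontier
  repeat {
    grown <- outside
    grown[-1, ] <- grown[-1, ] | outside[-n, ]
    grown[-n, ] <- grown[-n, ] | outside[-1, ]
    grown[, -1] <- grown[, -1] | outside[, -m]
    grown[, -m] <- grown[, -m] | outside[, -1]
    grown <- grown & !mask
    if (identical(grown, outside)) break
    outside <- grown
  }
  !outside
}

#' One ordered-subsets TOF-MLEM activity sub-update
#'
#' Classic EM ratio update restricted to one angular subset:
#' `lambda_j <- lambda_j / s_j * sum_i a_i p_ij w_ijt y_it / ybar_it` with
#' `s_j` the subset TOF sensitivity `sum_{i,t} a_i p_ij w_ijt` and `ybar`
#' the attenuated TOF forward projection including the additive term.
#' Non-negativity is preserved; pixels with zero sensitivity are unchanged.
#'
#' @param activity current activity matrix (>= 0), kBq/cc.
#' @param mu attenuation matrix used for correction, 1/cm.
#' @param data a [tof_sinogram()].
#' @param subset subset index in `1..n_subsets`.
#' @param n_subsets number of ordered subsets.
#' @return updated activity matrix.
#' @export
mlem_activity_update <- function(activity, mu, data, subset = 1L,
                                 n_subsets = 1L) {
  stopifnot(inherits(data, "tof_sinogram"))
  if (any(activity < 0)) stop("activity must be non-negative")
  if (any(data$counts < 0)) stop("negative counts")
  geometry <- data$geometry
  check_subsets(geometry, n_subsets)
  ang <- subset_angles(geometry, n_subsets, subset)
  a <- attenuation_factors(mu, geometry, ang)
  .mlem_sub(activity, a, data, ang)
}

# worker: MLEM sub-update with precomputed attenuation factors
.mlem_sub <- function(activity, a, data, ang) {
  geometry <- data$geometry
  y <- data$counts[, ang, , drop = FALSE]
  s <- data$additive[, ang, , drop = FALSE]
  ybar <- cpp_fp_tof(geometry, activity, ang) * as.vector(a) * data$calib + s
  ratio <- array(0, dim(y))
  pos <- ybar > 0
  ratio[pos] <- y[pos] / ybar[pos]
  bp <- cpp_bp_tof(geometry, as.vector(ratio * as.vector(a)), ang) * data$calib
  sens <- cpp_bp_tofsum(geometry, a, ang) * data$calib
  upd <- activity
  ok <- sens > 0
  upd[ok] <- activity[ok] * bp[ok] / sens[ok]
  upd
}

#' One ordered-subsets MLTR attenuation sub-update
#'
#' Additive Newton-type transmission update on the TOF-summed data:
#' `mu_j <- mu_j + relax * [sum_i l_ij (ybar_i - y_i)] /
#' [sum_i l_ij (sum_k l_ik) ybar_i]` over the subset's LORs, with `ybar` the
#' expected non-TOF counts at the current `(activity, mu)` including the
#' additive term and `l` chord lengths in cm.  The result is clipped to
#' `[0, mu_cap]`; pixels in the frozen mask are not updated.
#'
#' @param mu current attenuation matrix, 1/cm.
#' @param activity current activity matrix (held fixed), kBq/cc.
#' @param data a [tof_sinogram()].
#' @param subset subset index in `1..n_subsets`.
#' @param n_subsets number of ordered subsets.
#' @param frozen logical matrix of pixels excluded from the update.
#' @param relaxation step damping factor.
#' @param mu_cap upper clip, 1/cm.
#' @param domain optional logical matrix restricting the estimation domain:
#'   the surrogate chord `sum_k l_ik` is taken over the domain only (pixels
#'   outside are known air and are never updated), which makes the Newton
#'   steps scale with the object rather than with the full grid chord.
#' @return updated attenuation matrix.
#' @export
mltr_attenuation_update <- function(mu, activity, data, subset = 1L,
                                    n_subsets = 1L, frozen = NULL,
                                    relaxation = 1, mu_cap = 0.5,
                                    domain = NULL) {
  stopifnot(inherits(data, "tof_sinogram"))
  geometry <- data$geometry
  check_subsets(geometry, n_subsets)
  ang <- subset_angles(geometry, n_subsets, subset)
  y_nt <- apply(data$counts[, ang, , drop = FALSE], c(1, 2), sum)
  s_nt <- apply(data$additive[, ang, , drop = FALSE], c(1, 2), sum)
  dom_img <- matrix(1, geometry$grid_n, geometry$grid_n)
  if (!is.null(domain)) {
    dom_img[!domain] <- 0
    frozen <- if (is.null(frozen)) !domain else (frozen | !domain)
  }
  chord <- cpp_fp_line(geometry, dom_img, ang) / 10
  .mltr_sub(mu, activity, data, ang, y_nt, s_nt, chord, frozen, relaxation, mu_cap)
}

# worker: MLTR sub-update with precomputed TOF-summed data and chords (cm);
# the expected counts use the TOF-mass-weighted line integral so they match
# the TOF-binned emission model exactly after summing over TOF bins
.mltr_sub <- function(mu, activity, data, ang, y_nt, s_nt, chord,
                      frozen, relaxation, mu_cap) {
  geometry <- data$geometry
  q <- cpp_fp_tofsum(geometry, activity, ang)        # unattenuated, mm units
  a <- exp(-cpp_fp_line(geometry, mu, ang) / 10)
  ybar <- data$calib * q * a + s_nt
  num <- cpp_bp_line(geometry, ybar - y_nt, ang) / 10
  den <- cpp_bp_line(geometry, chord * ybar, ang) / 10
  upd <- mu
  ok <- den > 0
  if (!is.null(frozen)) ok <- ok & !frozen
  upd[ok] <- mu[ok] + relaxation * num[ok] / den[ok]
  pmin(pmax(upd, 0), mu_cap)
}

#' TOF-OSEM reconstruction with a supplied attenuation map
#'
#' The clinical reference method: ordered-subsets TOF-MLEM with attenuation
#' correction from an externally supplied ("CT") attenuation map, followed by
#' Gaussian post-filtering.  Deterministic given the data.
#'
#' @param data a [tof_sinogram()].
#' @param mu attenuation map used for correction, 1/cm.
#' @param control a [recon_control()].
#' @param roi optional logical matrix; its mean activity is traced per
#'   iteration.
#' @return an object of class `pet_recon` with elements `activity`
#'   (post-filtered), `activity_unfiltered`, `mu` (the supplied map),
#'   `diagnostics` (per-iteration log-likelihood and ROI mean),
#'   `iterations` (list of post-filtered snapshots if requested), `method`,
#'   `control`, `geometry`.
#' @export
tof_osem <- function(data, mu, control = recon_control(), roi = NULL) {
  stopifnot(inherits(data, "tof_sinogram"), inherits(control, "recon_control"))
  geometry <- data$geometry
  check_image(mu, geometry, "mu")
  check_subsets(geometry, control$n_subsets)
  if (any(data$counts < 0)) stop("negative counts")

  ns <- control$n_subsets
  sub_a <- lapply(seq_len(ns), function(s)
    attenuation_factors(mu, geometry, subset_angles(geometry, ns, s)))

  fov <- fov_mask(geometry)
  lambda <- matrix(0, geometry$grid_n, geometry$grid_n)
  # flat start scaled so the forward model matches the measured trues total
  unit <- matrix(0, geometry$grid_n, geometry$grid_n)
  unit[fov] <- 1
  denom <- sum(forward_project(unit, mu, geometry, calib = data$calib))
  c0 <- if (denom > 0) max(sum(data$counts) - sum(data$additive), 0) / denom else 0
  lambda[fov] <- c0

  diag_ll <- numeric(0)
  diag_roi <- numeric(0)
  snaps <- list()
  for (it in seq_len(control$n_iterations)) {
    for (s in seq_len(ns)) {
      ang <- subset_angles(geometry, ns, s)
      lambda <- .mlem_sub(lambda, sub_a[[s]], data, ang)
    }
    if (control$track_loglik) {
      ybar <- forward_project(lambda, mu, geometry,
                              additive = data$additive, calib = data$calib)
      diag_ll <- c(diag_ll, poisson_loglik(data$counts, ybar))
    }
    if (!is.null(roi)) diag_roi <- c(diag_roi, mean(lambda[roi]))
    if (control$keep_iterations)
      snaps[[it]] <- gaussian_postfilter(lambda, control$postfilter_fwhm_mm,
                                         geometry$pixel_size)
  }
  filtered <- gaussian_postfilter(lambda, control$postfilter_fwhm_mm,
                                  geometry$pixel_size)
  new_pet_recon("CT-OSEM", filtered, lambda, mu, NULL, diag_ll, diag_roi,
                snaps, control, geometry, data)
}

#' Total-activity scale prior from a reference reconstruction
#'
#' Runs [tof_osem()] with the reference attenuation map and sums the
#' (unfiltered) activity times voxel volume over pixels outside the
#' exclusion mask, giving the total tracer activity (kBq) used as the MLAA
#' scale constraint.
#'
#' @inheritParams tof_osem
#' @param reference_mu reference ("CT") attenuation map, 1/cm.
#' @return scalar total activity in kBq.
#' @export
compute_total_activity_prior <- function(data, reference_mu,
                                         control = recon_control()) {
  res <- tof_osem(data, reference_mu,
                  modifyList(control, list(keep_iterations = FALSE,
                                           track_loglik = FALSE)))
  mask <- exclusion_mask_from_mu(reference_mu, control$exclusion_thresholds)
  sum(res$activity_unfiltered[!mask]) * voxel_cc(data$geometry)
}

#' Rescale activity so its masked total matches a target
#'
#' Multiplies the activity by `target / current` where `current` is the
#' summed activity times voxel volume outside the exclusion mask; after the
#' call the masked total equals the target exactly.  The attenuation image
#' is left for subsequent MLTR updates to re-balance.
#'
#' @param activity activity matrix, kBq/cc.
#' @param target_total target total activity, kBq (> 0).
#' @param geometry a [pet_geometry()].
#' @param mask logical exclusion mask (`TRUE` = excluded), or `NULL`.
#' @return rescaled activity matrix.
#' @export
apply_scale_constraint <- function(activity, target_total, geometry,
                                   mask = NULL) {
  stopifnot(target_total > 0)
  keep <- if (is.null(mask)) activity else activity[!mask]
  cur <- sum(keep) * voxel_cc(geometry)
  if (cur == 0) stop("current masked activity total is zero; cannot rescale")
  activity * (target_total / cur)
}

#' MLAA joint activity/attenuation reconstruction
#'
#' Maximum-likelihood joint estimation of the tracer activity and the 511 keV
#' attenuation map from TOF emission data alone.  The estimation support is
#' first taken from the data by [estimate_support()] (the object's visible
#' hull from the scatter-corrected projections).  Activity and attenuation
#' are initialized uniform on that support (the activity level set by the
#' scale prior, the attenuation at water); outside the support both stay
#' zero, and the MLTR surrogate
#' curvature uses chord lengths through the support only, so the Newton
#' steps scale with the object rather than the full grid.  Each ordered
#' subset performs one TOF-MLEM activity sub-update followed by one MLTR
#' attenuation sub-update (or full sweeps per iteration, see
#' [recon_control()]); after every full iteration the activity is rescaled
#' so its total outside the exclusion mask equals the total-activity prior,
#' resolving the global scale ambiguity of the joint TOF problem.  Pixels
#' flagged by the exclusion mask (from the reference attenuation map) are
#' frozen in the MLTR update.  The final activity is Gaussian post-filtered.
#'
#' @inheritParams tof_osem
#' @param reference_mu reference ("CT") attenuation map used only to build
#'   the exclusion mask and, when `control$total_activity_prior` is `NULL`,
#'   the scale prior via [compute_total_activity_prior()].  May be `NULL`
#'   when the prior is supplied directly (the exclusion mask is then empty).
#' @return a `pet_recon` object; `mu` holds the jointly estimated
#'   attenuation map (before post-filtering).
#' @export
mlaa <- function(data, reference_mu = NULL, control = recon_control(),
                 roi = NULL) {
  stopifnot(inherits(data, "tof_sinogram"), inherits(control, "recon_control"))
  geometry <- data$geometry
  check_subsets(geometry, control$n_subsets)
  if (any(data$counts < 0)) stop("negative counts")

  prior <- control$total_activity_prior
  if (is.null(prior)) {
    if (is.null(reference_mu))
      stop("either a total_activity_prior or a reference_mu is required")
    prior <- compute_total_activity_prior(data, reference_mu, control)
  }
  mask <- if (is.null(reference_mu)) NULL
          else exclusion_mask_from_mu(reference_mu, control$exclusion_thresholds)

  support <- estimate_support(data, control$support_threshold)
  frozen <- if (is.null(mask)) !support else (!support | mask)

  lambda <- matrix(0, geometry$grid_n, geometry$grid_n)
  lambda[support] <- prior / (sum(support) * voxel_cc(geometry))
  mu <- matrix(0, geometry$grid_n, geometry$grid_n)
  mu[support] <- control$mu_init

  ns <- control$n_subsets
  y_nt <- vector("list", ns)
  s_nt <- vector("list", ns)
  chords <- vector("list", ns)
  supp_img <- matrix(0, geometry$grid_n, geometry$grid_n)
  supp_img[support] <- 1
  for (s in seq_len(ns)) {
    ang <- subset_angles(geometry, ns, s)
    y_nt[[s]] <- apply(data$counts[, ang, , drop = FALSE], c(1, 2), sum)
    s_nt[[s]] <- apply(data$additive[, ang, , drop = FALSE], c(1, 2), sum)
    chords[[s]] <- cpp_fp_line(geometry, supp_img, ang) / 10
  }

  diag_ll <- numeric(0)
  diag_roi <- numeric(0)
  snaps <- list()
  for (it in seq_len(control$n_iterations)) {
    for (s in seq_len(ns)) {
      ang <- subset_angles(geometry, ns, s)
      a <- attenuation_factors(mu, geometry, ang)
      lambda <- .mlem_sub(lambda, a, data, ang)
      if (control$interleave == "per-subset")
        mu <- .mltr_sub(mu, lambda, data, ang, y_nt[[s]], s_nt[[s]],
                        chords[[s]], frozen, control$mltr_relaxation,
                        control$mu_cap)
    }
    if (control$interleave == "per-iteration") {
      for (s in seq_len(ns)) {
        ang <- subset_angles(geometry, ns, s)
        mu <- .mltr_sub(mu, lambda, data, ang, y_nt[[s]], s_nt[[s]],
                        chords[[s]], frozen, control$mltr_relaxation,
                        control$mu_cap)
      }
    }
    lambda <- apply_scale_constraint(lambda, prior, geometry, mask)
    if (control$track_loglik) {
      ybar <- forward_project(lambda, mu, geometry,
                              additive = data$additive, calib = data$calib)
      diag_ll <- c(diag_ll, poisson_loglik(data$counts, ybar))
    }
    if (!is.null(roi)) diag_roi <- c(diag_roi, mean(lambda[roi]))
    if (control$keep_iterations)
      snaps[[it]] <- gaussian_postfilter(lambda, control$postfilter_fwhm_mm,
                                         geometry$pixel_size)
  }
  filtered <- gaussian_postfilter(lambda, control$postfilter_fwhm_mm,
                                  geometry$pixel_size)
  res <- new_pet_recon("MLAA", filtered, lambda, mu, mask, diag_ll, diag_roi,
                       snaps, control, geometry, data)
  res$total_activity_prior <- prior
  res
}

new_pet_recon <- function(method, activity, unfiltered, mu, mask,
                          diag_ll, diag_roi, snaps, control, geometry, data) {
  structure(list(method = method,
                 activity = activity,
                 activity_unfiltered = unfiltered,
                 mu = mu,
                 exclusion_mask = mask,
                 diagnostics = list(loglik = diag_ll, roi_mean = diag_roi),
                 iterations = snaps,
                 control = control,
                 geometry = geometry,
                 data = data),
            class = "pet_recon")
}
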