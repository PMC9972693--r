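#' @export
print.pet_recon <- function(x, ...) {
  cat(sprintf("%s reconstruction (%d iterations x %d subsets, %.1f mm post-filter)\n",
              x$method, x$control$n_iterations, x$control$n_subsets,
              x$control$postfilter_fwhm_mm))
  cat(sprintf("  activity : %d x %d, range [%.3g, %.3g] kBq/cc\n",
              nrow(x$activity), ncol(x$activity),
              min(x$activity), max(x$activity)))
  if (x$method == "MLAA")
    cat(sprintf("  mu       : jointly estimated, range [%.3g, %.3g] /cm; prior total %.4g kBq\n",
                min(x$mu), max(x$mu), x$total_activity_prior))
  if (length(x$diagnostics$loglik))
    cat(sprintf("  loglik   : %s\n",
                paste(sprintf("%.6g", x$diagnostics$loglik), collapse = " -> ")))
  invisible(x)
}

#' @export
summary.pet_recon <- function(object, ...) {
  fov <- fov_mask(object$geometry)
  s <- list(method = object$method,
            n_iterations = object$control$n_iterations,
            n_subsets = object$control$n_subsets,
            activity_total_kBq = sum(object$activity) * voxel_cc(object$geometry),
            activity_range = range(object$activity),
            mean_in_fov = mean(object$activity[fov]),
            loglik = object$diagnostics$loglik)
  class(s) <- "summary.pet_recon"
  s
}

#' @export
print.summary.pet_recon <- function(x, ...) {
  cat(sprintf("%s: %d it x %d subsets\n", x$method, x$n_iterations, x$n_subsets))
  cat(sprintf("  total activity %.4g kBq; FOV mean %.4g kBq/cc; range [%.3g, %.3g]\n",
              x$activity_total_kBq, x$mean_in_fov,
              x$activity_range[1], x$activity_range[2]))
  if (length(x$loglik))
    cat(sprintf("  final log-likelihood %.6g\n", x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Expected sinogram of a reconstruction
#'
#' The attenuated TOF forward projection of the reconstructed (unfiltered)
#' activity, including the additive term — the fitted Poisson mean.
#' @param object a `pet_recon`.
#' @param ... unused.
#' @export
fitted.pet_recon <- function(object, ...) {
  forward_project(object$activity_unfiltered, object$mu, object$geometry,
                  additive = object$data$additive, calib = object$data$calib)
}

#' Raw residuals of a reconstruction
#'
#' Observed minus fitted sinogram counts.
#' @param object a `pet_recon`.
#' @param ... unused.
#' @export
residuals.pet_recon <- function(object, ...) {
  object$data$counts - fitted(object)
}

#' @export
logLik.pet_recon <- function(object, ...) {
  ll <- poisson_loglik(object$data$counts, fitted(object))
  structure(ll, class = "logLik", df = NA_integer_,
            nobs = length(object$data$counts))
}

#' Display a reconstruction
#'
#' Shows the post-filtered activity image (and, for MLAA, the estimated
#' attenuation map) with [graphics::image()].
#' @param x a `pet_recon`.
#' @param what `"activity"` or `"mu"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.pet_recon <- function(x, what = c("activity", "mu"), ...) {
  what <- match.arg(what)
  img <- if (what == "activity") x$activity else x$mu
  xc <- pixel_centers(x$geometry)
  graphics::image(xc, xc, img, asp = 1, col = grDevices::gray.colors(128),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("%s %s", x$method, what), ...)
  invisible(x)
}
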