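#' Region of interest on the image grid
#'
#' @param name ROI name.
#' @param mask non-empty logical matrix on the image grid.
#' @param tag anatomical tag: `"organ"`, `"lesion"`, `"dome"`, `"middle"` or
#'   `"implant-adjacent"`.
#' @export
roi <- function(name, mask,
                tag = c("organ", "lesion", "dome", "middle", "implant-adjacent")) {
  tag <- match.arg(tag)
  if (!is.logical(mask) || !any(mask)) stop("ROI mask must be a non-empty logical matrix")
  structure(list(name = name, mask = mask, tag = tag), class = "pet_roi")
}

#' Disk-shaped ROI
#'
#' @param name ROI name.
#' @param cx,cy centre in mm (scanner coordinates).
#' @param r radius in mm.
#' @param geometry a [pet_geometry()].
#' @param tag anatomical tag (see [roi()]).
#' @export
disk_roi <- function(name, cx, cy, r, geometry, tag = "organ") {
  rg <- phantom_region(name, "disk", c(cx = cx, cy = cy, r = r), 0, 0)
  roi(name, region_mask(rg, geometry), tag)
}

#' Standardized uptake value from a concentration
#'
#' `SUV = concentration * body_weight / injected_dose` with the 1 g = 1 cc
#' convention (concentration in kBq/cc, weight in g, dose in kBq).
#'
#' @param concentration_kBq_cc tracer concentration.
#' @param injected_dose_kBq injected dose, kBq (> 0).
#' @param body_weight_g body weight, g (> 0).
#' @return unitless SUV.
#' @export
suv_from_concentration <- function(concentration_kBq_cc, injected_dose_kBq,
                                   body_weight_g) {
  if (injected_dose_kBq <= 0) stop("injected dose must be positive")
  if (body_weight_g <= 0) stop("body weight must be positive")
  concentration_kBq_cc * body_weight_g / injected_dose_kBq
}

#' SUVmean and SUVmax over an ROI
#'
#' Mean and maximum of the image over the ROI mask, converted to SUV when
#' dose and weight are given (otherwise raw concentrations are reported,
#' i.e. an SUV factor of 1).
#'
#' @param image activity image matrix.
#' @param roi a [roi()].
#' @param injected_dose_kBq,body_weight_g optional SUV conversion inputs.
#' @param source optional reconstruction id recorded in the result.
#' @return list with `suv_mean`, `suv_max`, `n`, `roi`, `source`.
#' @export
roi_stats <- function(image, roi, injected_dose_kBq = NULL,
                      body_weight_g = NULL, source = NULL) {
  stopifnot(inherits(roi, "pet_roi"))
  if (!any(roi$mask)) stop("empty ROI mask")
  v <- image[roi$mask]
  if (!is.null(injected_dose_kBq) && !is.null(body_weight_g))
    v <- suv_from_concentration(v, injected_dose_kBq, body_weight_g)
  list(suv_mean = mean(v), suv_max = max(v), n = length(v),
       roi = roi$name, source = source)
}

#' Percent SUV difference between two reconstructions
#'
#' Absolute relative difference with the reference method in the
#' denominator: `|suv_mlaa - suv_ctosem| / suv_ctosem * 100`.
#'
#' @param suv_mlaa SUV from the joint reconstruction.
#' @param suv_ctosem SUV from the reference reconstruction (> 0).
#' @return percent difference (>= 0).
#' @export
suv_difference <- function(suv_mlaa, suv_ctosem) {
  if (any(suv_ctosem <= 0)) stop("reference SUV must be positive")
  abs(suv_mlaa - suv_ctosem) / suv_ctosem * 100
}

#' Percent liver SUV variation between dome and middle
#'
#' `|suv_dome - suv_middle| / suv_middle * 100`, the middle of the liver
#' serving as the within-image reference.
#'
#' @param suv_dome SUV at the dome of the liver.
#' @param suv_middle SUV at the middle of the liver (> 0).
#' @return percent variation (>= 0).
#' @export
liver_suv_variation <- function(suv_dome, suv_middle) {
  if (any(suv_middle <= 0)) stop("middle-liver SUV must be positive")
  abs(suv_dome - suv_middle) / suv_middle * 100
}

#' 40% threshold lesion delineation
#'
#' Pixels of the search region whose value reaches 40% of the regional peak,
#' restricted to the 4-connected component containing the peak.
#'
#' @param image activity image matrix.
#' @param search_region logical matrix containing the lesion peak.
#' @param threshold relative threshold (default 0.40).
#' @return a lesion [roi()].
#' @export
lesion_mask_40pct <- function(image, search_region, threshold = 0.40) {
  stopifnot(is.logical(search_region), any(search_region))
  vmax <- max(image[search_region])
  if (vmax <= 0) stop("search region contains no positive values")
  cand <- search_region & image >= threshold * vmax
  peak <- which(search_region & image == vmax)[1]
  comp <- connected_component(cand, peak)
  roi("lesion_40pct", comp, "lesion")
}

# 4-connected component of a logical mask containing a linear seed index
connected_component <- function(mask, seed) {
  n <- nrow(mask)
  m <- ncol(mask)
  comp <- matrix(FALSE, n, m)
  comp[seed] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-n, ]
    grown[-n, ] <- grown[-n, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -m]
    grown[, -m] <- grown[, -m] | comp[, -1]
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Per-ROI linear regression between two reconstructions
#'
#' Ordinary least squares of the joint-reconstruction SUVs on the reference
#' SUVs (with intercept), plus the squared Pearson correlation — the slope
#' `k` and `R^2` used to summarize the agreement of the two methods.
#'
#' @param x reference (CT-OSEM) SUVs.
#' @param y joint-reconstruction (MLAA) SUVs.
#' @return object of class `suv_regression`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
suv_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 points are required")
  if (stats::sd(x) == 0) stop("degenerate regression: constant x")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = cor(x, y)^2,
                 n = length(x)),
            class = "suv_regression")
}

#' @export
print.suv_regression <- function(x, ...) {
  cat(sprintf("SUV regression: k = %.4f, intercept = %.4f, R^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Ground-truth ROI set for a torso phantom
#'
#' Builds the evaluation ROIs from the truth label map: the organ ROIs
#' (lungs, liver excluding its dome band and lesions, spine, a soft-tissue
#' disk), every lesion, and the dome and middle liver disks used for the
#' dome-versus-middle variation (both placed to avoid lesions).  ROIs are
#' defined once on the truth labels and applied identically to both
#' reconstructions.
#'
#' @param truth a [rasterize_phantom()] truth bundle for a torso phantom.
#' @param geometry a [pet_geometry()].
#' @param dome_r,middle_r disk radii in mm for the dome and middle liver
#'   ROIs.
#' @return named list of [roi()] objects.
#' @export
torso_rois <- function(truth, geometry, dome_r = 8, middle_r = 12) {
  ln <- truth$label_names
  lab <- truth$labels
  rois <- list()
  for (organ in c("lung_left", "lung_right", "spine")) {
    i <- match(organ, ln)
    rois[[organ]] <- roi(organ, lab == i, "organ")
  }
  liver_i <- match("liver", ln)
  dome_rows <- torso_dome_rows(truth)
  liver_mask <- lab == liver_i
  dome_band <- matrix(FALSE, nrow(lab), ncol(lab))
  dome_band[, dome_rows] <- TRUE
  rois$liver <- roi("liver", liver_mask & !dome_band, "organ")

  # soft-tissue sample: disk low in the abdomen, left of the spine
  rois$soft_tissue <- disk_roi("soft_tissue", -70, -90, 18, geometry, "organ")

  lesion_idx <- grep("^lesion", ln)
  for (i in lesion_idx) rois[[ln[i]]] <- roi(ln[i], lab == i, "lesion")

  # dome / middle liver disks avoiding lesions
  place_disk <- function(name, rows, r, tag) {
    zone <- liver_mask
    zone[, setdiff(seq_len(ncol(lab)), rows)] <- FALSE
    ctr <- centroid_fit(zone, r, geometry)
    disk_roi(name, ctr[1], ctr[2], r, geometry, tag)
  }
  mid_rows <- liver_rows_middle(truth)
  rois$dome <- place_disk("dome", dome_rows, dome_r, "dome")
  rois$middle <- place_disk("middle", mid_rows, middle_r, "middle")
  rois
}

liver_rows_middle <- function(truth) {
  liver_i <- match("liver", truth$label_names)
  rows <- which(apply(truth$labels == liver_i, 2, any))
  h <- length(rows)
  mid <- rows[rows >= min(rows) + floor(0.35 * h) & rows <= max(rows) - ceiling(0.3 * h)]
  mid
}

# centre of the largest inscribed disk-ish position: the zone pixel whose
# minimum distance to the zone boundary is largest (coarse erosion search)
centroid_fit <- function(zone, r, geometry) {
  xc <- pixel_centers(geometry)
  idx <- which(zone, arr.ind = TRUE)
  pts <- cbind(xc[idx[, 1]], xc[idx[, 2]])
  out_idx <- which(!zone, arr.ind = TRUE)
  out <- cbind(xc[out_idx[, 1]], xc[out_idx[, 2]])
  # subsample the outside for speed; boundary pixels dominate the minimum
  keep <- seq(1, nrow(out), by = max(1L, nrow(out) %/% 4000))
  out <- out[keep, , drop = FALSE]
  d <- apply(pts, 1, function(p) min(sqrt((out[, 1] - p[1])^2 + (out[, 2] - p[2])^2)))
  pts[which.max(d), ]
}

#' MLAA convergence curve over iteration counts
#'
#' Runs [mlaa()] once at the maximum requested iteration count, storing the
#' post-filtered activity after every iteration (each snapshot is exactly
#' the reconstruction that the same control stopped at that count would
#' return), and reports the ROI mean per iteration count; optionally the
#' same for [tof_osem()].
#'
#' @param data a [tof_sinogram()].
#' @param reference_mu reference attenuation map.
#' @param iterations integer vector of iteration counts (e.g. `1:7`).
#' @param roi logical matrix of the evaluation ROI.
#' @param control a [recon_control()]; its `n_iterations` is overridden.
#' @param include_osem also trace the reference TOF-OSEM.
#' @return data.frame with columns `method`, `iterations`, `roi_mean`.
#' @export
convergence_curve <- function(data, reference_mu, iterations = 1:7, roi,
                              control = recon_control(),
                              include_osem = FALSE) {
  stopifnot(length(iterations) >= 1, all(iterations >= 1))
  it_max <- max(iterations)
  ctl <- modifyList(control, list(n_iterations = as.integer(it_max),
                                  keep_iterations = TRUE,
                                  track_loglik = FALSE))
  fit <- mlaa(data, reference_mu, ctl)
  out <- data.frame(method = "MLAA", iterations = iterations,
                    roi_mean = vapply(iterations,
                                      function(k) mean(fit$iterations[[k]][roi]),
                                      numeric(1)))
  if (include_osem) {
    fo <- tof_osem(data, reference_mu, ctl)
    out <- rbind(out, data.frame(method = "CT-OSEM", iterations = iterations,
                                 roi_mean = vapply(iterations,
                                                   function(k) mean(fo$iterations[[k]][roi]),
                                                   numeric(1))))
  }
  out
}

#' Quantitative comparison report for two reconstructions
#'
#' Assembles the per-ROI SUV statistics of the joint and reference
#' reconstructions, their percent SUV differences, the liver
#' dome-versus-middle variation for both methods, and the agreement
#' regressions: over organ ROIs, over all lesions, and over lesions split
#' into motion-affected (dome or lung-base rows) versus non-motion-affected
#' groups.
#'
#' @param truth a truth bundle from [simulate_acquisition()].
#' @param recon_mlaa,recon_osem `pet_recon` objects sharing the grid.
#' @param rois named list of [roi()] objects (see [torso_rois()]).
#' @param injected_dose_kBq,body_weight_g optional SUV conversion (defaults
#'   taken from the phantom when present).
#' @return list of data.frames `comparisons`, `variations`, `regressions`.
#' @export
experiment_report <- function(truth, recon_mlaa, recon_osem, rois,
                              injected_dose_kBq = NULL, body_weight_g = NULL) {
  if (!all(dim(recon_mlaa$activity) == dim(recon_osem$activity)))
    stop("reconstructions do not share the image grid")
  ph <- truth$phantom
  if (is.null(injected_dose_kBq) && !is.null(ph)) injected_dose_kBq <- ph$injected_dose_kBq
  if (is.null(body_weight_g) && !is.null(ph)) body_weight_g <- ph$body_weight_g

  rows <- lapply(names(rois), function(nm) {
    r <- rois[[nm]]
    sm <- roi_stats(recon_mlaa$activity, r, injected_dose_kBq, body_weight_g, "MLAA")
    so <- roi_stats(recon_osem$activity, r, injected_dose_kBq, body_weight_g, "CT-OSEM")
    st <- roi_stats(truth$activity, r, injected_dose_kBq, body_weight_g, "truth")
    data.frame(roi = nm, tag = r$tag,
               suv_mean_mlaa = sm$suv_mean, suv_max_mlaa = sm$suv_max,
               suv_mean_osem = so$suv_mean, suv_max_osem = so$suv_max,
               suv_mean_truth = st$suv_mean, suv_max_truth = st$suv_max,
               diff_mean_pct = suv_difference(sm$suv_mean, so$suv_mean),
               diff_max_pct = suv_difference(sm$suv_max, so$suv_max),
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, rows)

  variations <- NULL
  tags <- vapply(rois, function(r) r$tag, character(1))
  if ("dome" %in% tags && "middle" %in% tags) {
    dome <- rois[[which(tags == "dome")[1]]]
    middle <- rois[[which(tags == "middle")[1]]]
    var_row <- function(fit, method) {
      sd_ <- roi_stats(fit$activity, dome, injected_dose_kBq, body_weight_g)
      sm_ <- roi_stats(fit$activity, middle, injected_dose_kBq, body_weight_g)
      data.frame(method = method,
                 variation_mean_pct = liver_suv_variation(sd_$suv_mean, sm_$suv_mean),
                 variation_max_pct = liver_suv_variation(sd_$suv_max, sm_$suv_max),
                 stringsAsFactors = FALSE)
    }
    variations <- rbind(var_row(recon_mlaa, "MLAA"), var_row(recon_osem, "CT-OSEM"))
  } else {
    warning("dome/middle ROIs missing; variation rows omitted")
  }

  reg_row <- function(sub, group) {
    if (nrow(sub) < 3) return(NULL)
    rbind(
      data.frame(group = group, statistic = "SUVmean",
                 slope = suv_regression(sub$suv_mean_osem, sub$suv_mean_mlaa)$slope,
                 intercept = suv_regression(sub$suv_mean_osem, sub$suv_mean_mlaa)$intercept,
                 r_squared = suv_regression(sub$suv_mean_osem, sub$suv_mean_mlaa)$r_squared,
                 n = nrow(sub), stringsAsFactors = FALSE),
      data.frame(group = group, statistic = "SUVmax",
                 slope = suv_regression(sub$suv_max_osem, sub$suv_max_mlaa)$slope,
                 intercept = suv_regression(sub$suv_max_osem, sub$suv_max_mlaa)$intercept,
                 r_squared = suv_regression(sub$suv_max_osem, sub$suv_max_mlaa)$r_squared,
                 n = nrow(sub), stringsAsFactors = FALSE))
  }
  organs <- comparisons[comparisons$tag == "organ", ]
  lesions <- comparisons[comparisons$tag == "lesion", ]
  regs <- list(reg_row(organs, "organs"), reg_row(lesions, "lesions_all"))
  if (nrow(lesions) > 0 && !is.null(truth$labels)) {
    motion <- vapply(lesions$roi, function(nm)
      lesion_motion_affected(rois[[nm]], truth), logical(1))
    regs <- c(regs, list(reg_row(lesions[motion, ], "lesions_motion"),
                         reg_row(lesions[!motion, ], "lesions_nonmotion")))
  }
  regressions <- do.call(rbind, regs[!vapply(regs, is.null, logical(1))])

  list(comparisons = comparisons, variations = variations,
       regressions = regressions)
}

# a lesion is motion-affected iff it intersects the liver-dome rows or the
# lung-base rows (bottom quarter of the lung fields)
lesion_motion_affected <- function(lesion_roi, truth) {
  rows <- which(apply(lesion_roi$mask, 2, any))
  dome <- torso_dome_rows(truth)
  lung_i <- match(c("lung_left", "lung_right"), truth$label_names)
  lung_rows <- which(apply(matrix(truth$labels %in% lung_i,
                                  nrow(truth$labels)), 2, any))
  base <- lung_rows[lung_rows < min(lung_rows) + ceiling(0.25 * length(lung_rows))]
  any(rows %in% dome) || any(rows %in% base)
}
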