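#' End-to-end experiment configuration
#'
#' A declarative description of one simulated experiment: which scenario to
#' generate, the acquisition statistics, the reconstruction protocol and the
#' mismatch parameters.  Configurations round-trip losslessly through YAML
#' ([write_experiment_config()] / [read_experiment_config()]), and
#' [run_experiment()] is deterministic given a configuration — all
#' randomness flows through the recorded seed.
#'
#' @param scenario one of `"cylinder"`, `"torso-matched"`,
#'   `"torso-respiratory"`, `"torso-metal"`.
#' @param counts expected true counts.
#' @param scatter_fraction additive (scatter) fraction in `[0, 1)`.
#' @param seed integer seed (mandatory; no clock seeding).
#' @param iterations,subsets,fwhm reconstruction protocol for both methods.
#' @param shift_mm respiratory dome shift (torso-respiratory).
#' @param implant_inflation attenuation inflation factor (torso-metal).
#' @param convergence_iterations iteration sweep for the cylinder scenario.
#' @param geometry a [pet_geometry()] (stored by its fields).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("cylinder", "torso-matched",
                                           "torso-respiratory", "torso-metal"),
                              counts = 2e6, scatter_fraction = 0.2,
                              seed = 1L, iterations = 3L, subsets = 10L,
                              fwhm = 4.5, shift_mm = 12,
                              implant_inflation = 3,
                              convergence_iterations = 1:7,
                              geometry = pet_geometry()) {
  scenario <- match.arg(scenario)
  stopifnot(counts > 0, scatter_fraction >= 0, scatter_fraction < 1,
            is.finite(seed))
  structure(list(scenario = scenario, counts = counts,
                 scatter_fraction = scatter_fraction, seed = as.integer(seed),
                 iterations = as.integer(iterations),
                 subsets = as.integer(subsets), fwhm = fwhm,
                 shift_mm = shift_mm, implant_inflation = implant_inflation,
                 convergence_iterations = as.integer(convergence_iterations),
                 geometry = unclass(geometry)[setdiff(names(unclass(geometry)),
                                                      "tof_sigma_mm")]),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML path.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @param config an `experiment_config` (for writing).
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  g <- x$geometry
  do.call(experiment_config,
          c(x[setdiff(names(x), "geometry")],
            list(geometry = do.call(pet_geometry, g))))
}

config_geometry <- function(config) do.call(pet_geometry, config$geometry)

#' Run a full simulated experiment
#'
#' Simulates the configured scenario, reconstructs with both CT-OSEM (using
#' the scenario's possibly corrupted "CT" attenuation map) and MLAA,
#' evaluates, and writes a versioned artifact directory: truth images and
#' the corrupted attenuation map as NIfTI, the sinogram container, both
#' reconstructions, the report CSVs and a JSON manifest with the
#' configuration, software version and per-file checksums.  Deterministic
#' given the configuration; partial outputs are removed on failure.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created; must not be an existing
#'   non-empty directory unless `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the in-memory results (`truth`, `data`,
#'   `recon_mlaa`, `recon_osem`, `report`, and `convergence` for the
#'   cylinder scenario).
#' @export
run_experiment <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty")
  started_fresh <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && started_fresh) unlink(out_dir, recursive = TRUE), add = TRUE)

  geometry <- config_geometry(config)
  ctl <- recon_control(n_iterations = config$iterations,
                       n_subsets = config$subsets,
                       postfilter_fwhm_mm = config$fwhm)

  if (config$scenario == "cylinder") {
    phantom <- make_uniform_cylinder(geometry = geometry)
    sim <- simulate_acquisition(phantom, geometry, config$counts,
                                config$scatter_fraction, config$seed)
    ct_mu <- sim$truth$mu
    roi_mask <- region_mask(phantom_region("roi", "disk",
                                           c(cx = 0, cy = 0, r = 75), 0, 0),
                            geometry)
  } else {
    phantom <- make_torso_phantom(config$seed, geometry)
    sim <- simulate_acquisition(phantom, geometry, config$counts,
                                config$scatter_fraction, config$seed)
    spec <- switch(config$scenario,
                   "torso-matched" = mismatch_spec("matched"),
                   "torso-respiratory" = mismatch_spec("respiratory",
                                                       shift_mm = config$shift_mm),
                   "torso-metal" = mismatch_spec("metal",
                                                 inflation = config$implant_inflation))
    ct_mu <- corrupt_mu_map(sim$truth$mu, spec, geometry,
                            dome_rows = torso_dome_rows(sim$truth))
    roi_mask <- NULL
  }

  recon_osem <- tof_osem(sim$data, ct_mu, ctl, roi = roi_mask)
  recon_mlaa <- mlaa(sim$data, ct_mu, ctl, roi = roi_mask)

  # persist inputs and reconstructions
  write_nifti_image(sim$truth$activity, file.path(out_dir, "truth_activity.nii"),
                    geometry, "kBq/cc")
  write_nifti_image(sim$truth$mu, file.path(out_dir, "truth_mu.nii"),
                    geometry, "1/cm")
  write_nifti_image(sim$truth$labels + 0, file.path(out_dir, "truth_labels.nii"),
                    geometry, "label")
  write_nifti_image(ct_mu, file.path(out_dir, "ct_mu.nii"), geometry, "1/cm")
  write_sinogram(sim$data, file.path(out_dir, "sinogram.json"))
  write_nifti_image(recon_osem$activity, file.path(out_dir, "ctosem_activity.nii"),
                    geometry, "kBq/cc")
  write_nifti_image(recon_mlaa$activity, file.path(out_dir, "mlaa_activity.nii"),
                    geometry, "kBq/cc")
  write_nifti_image(recon_mlaa$mu, file.path(out_dir, "mlaa_mu.nii"),
                    geometry, "1/cm")

  result <- list(truth = sim$truth, data = sim$data,
                 recon_mlaa = recon_mlaa, recon_osem = recon_osem)

  if (config$scenario == "cylinder") {
    conv <- convergence_curve(sim$data, ct_mu, config$convergence_iterations,
                              roi_mask, ctl, include_osem = TRUE)
    write.csv(conv, file.path(out_dir, "convergence.csv"), row.names = FALSE)
    recov <- data.frame(method = c("MLAA", "CT-OSEM"),
                        roi_mean_kBq_cc = c(mean(recon_mlaa$activity[roi_mask]),
                                            mean(recon_osem$activity[roi_mask])),
                        truth_kBq_cc = mean(sim$truth$activity[roi_mask]))
    write.csv(recov, file.path(out_dir, "recovery.csv"), row.names = FALSE)
    result$convergence <- conv
    result$recovery <- recov
  } else {
    rois <- torso_rois(sim$truth, geometry)
    if (config$scenario == "torso-metal") {
      spec <- mismatch_spec("metal", inflation = config$implant_inflation)
      imp <- region_mask(spec$implant, geometry)
      adj <- dilate_mask(imp, 2L)
      rois$implant_adjacent <- roi("implant_adjacent", adj, "implant-adjacent")
    }
    report <- experiment_report(sim$truth, recon_mlaa, recon_osem, rois)
    write.csv(report$comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
    if (!is.null(report$variations))
      write.csv(report$variations, file.path(out_dir, "variations.csv"),
                row.names = FALSE)
    write.csv(report$regressions, file.path(out_dir, "regressions.csv"),
              row.names = FALSE)
    result$report <- report
    result$rois <- rois
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_experiment_config(config, cfg_path)
  files <- setdiff(dir(out_dir), "manifest.json")
  manifest <- list(package = "mlaapet",
                   version = as.character(utils::packageVersion("mlaapet")),
                   scenario = config$scenario,
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(result)
}

# square dilation of a logical mask by k pixels
dilate_mask <- function(mask, k = 1L) {
  n <- nrow(mask)
  m <- ncol(mask)
  out <- mask
  for (i in seq_len(k)) {
    g <- out
    g[-1, ] <- g[-1, ] | out[-n, ]
    g[-n, ] <- g[-n, ] | out[-1, ]
    g[, -1] <- g[, -1] | out[, -m]
    g[, -m] <- g[, -m] | out[, -1]
    out <- g
  }
  out
}
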