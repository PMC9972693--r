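#' Write an image as single-slice NIfTI-1 with a JSON sidecar
#'
#' The matrix is stored as a 2D NIfTI-1 image with the pixel size in the
#' header; units and grid metadata go to a JSON sidecar next to the image.
#'
#' @param image `grid_n x grid_n` matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geometry a [pet_geometry()].
#' @param units unit string recorded in the sidecar (e.g. `"kBq/cc"`,
#'   `"1/cm"`).
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(image, path, geometry, units = "") {
  check_image(image, geometry, "image")
  im <- RNifti::asNifti(image)
  RNifti::pixdim(im) <- rep(geometry$pixel_size, length(dim(im)))
  RNifti::writeNifti(im, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(units = units,
                            pixel_size_mm = geometry$pixel_size,
                            grid_n = geometry$grid_n),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-slice NIfTI-1 image
#'
#' @param path NIfTI path written by [write_nifti_image()].
#' @return list with `image` (matrix), `pixel_size` (mm) and `units` (from
#'   the sidecar when present).
#' @export
read_nifti_image <- function(path) {
  im <- RNifti::readNifti(path)
  px <- RNifti::pixdim(im)[1]
  d <- dim(im)
  if (length(d) == 3 && d[3] == 1) im <- im[, , 1]
  units <- ""
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) units <- jsonlite::read_json(sidecar)$units
  list(image = matrix(as.numeric(im), d[1], d[2]),
       pixel_size = px, units = units)
}

#' Write a TOF sinogram as binary + JSON header
#'
#' Counts and the additive term are written as flat little-endian 64-bit
#' float arrays in radial-fastest order; the JSON header records the
#' dimensions, the geometry fields, the calibration factor and the file
#' names.
#'
#' @param sinogram a [tof_sinogram()].
#' @param path header path (`.json`); the binary payloads are written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sinogram, path) {
  stopifnot(inherits(sinogram, "tof_sinogram"))
  base <- sub("\\.json$", "", path)
  counts_file <- paste0(basename(base), "_counts.bin")
  additive_file <- paste0(basename(base), "_additive.bin")
  write_f64 <- function(x, f) {
    con <- file(f, "wb")
    on.exit(close(con))
    writeBin(as.double(as.vector(x)), con, size = 8, endian = "little")
  }
  write_f64(sinogram$counts, file.path(dirname(path), counts_file))
  write_f64(sinogram$additive, file.path(dirname(path), additive_file))
  g <- sinogram$geometry
  hdr <- list(format = "mlaapet-tof-sinogram-v1",
              order = "radial-fastest",
              dims = c(g$n_radial, g$n_angles, g$n_tof_bins),
              calib = sinogram$calib,
              counts_file = counts_file,
              additive_file = additive_file,
              geometry = unclass(g))
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TOF sinogram written by [write_sinogram()]
#'
#' @param path header path (`.json`).
#' @return a [tof_sinogram()].
#' @export
read_sinogram <- function(path) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(hdr$format) || hdr$format != "mlaapet-tof-sinogram-v1")
    stop("not a mlaapet sinogram header")
  dims <- as.integer(hdr$dims)
  g <- hdr$geometry
  geometry <- pet_geometry(g$n_radial, g$n_angles, g$radial_spacing,
                           g$fov_diameter, g$n_tof_bins, g$tof_bin_width,
                           g$tof_resolution_ps, g$grid_n, g$pixel_size)
  read_f64 <- function(f, n) {
    sz <- file.info(f)$size
    if (is.na(sz) || sz != 8 * n)
      stop(sprintf("binary payload %s does not match header dimensions", f))
    con <- file(f, "rb")
    on.exit(close(con))
    readBin(con, "double", n = n, size = 8, endian = "little")
  }
  n <- prod(dims)
  counts <- array(read_f64(file.path(dirname(path), hdr$counts_file), n), dims)
  additive <- array(read_f64(file.path(dirname(path), hdr$additive_file), n), dims)
  tof_sinogram(counts, additive, hdr$calib, geometry)
}
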