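#' Write a datacube container
#'
#' Stores the counts as little-endian float64 binary (`<path>`) plus a JSON
#' sidecar (`<path>.json`) holding the array dimensions and the calibration
#' attributes (scan_step_A, det_pixel_mrad, det_center, kV, alpha_mrad,
#' dose, seed). The round trip through [read_datacube()] is lossless.
#'
#' @param cube A [datacube4d()].
#' @param path Output file path (binary payload; sidecar gets `.json`).
#' @return `path`, invisibly.
#' @export
write_datacube <- function(cube, path) {
  d <- dim(cube$counts)
  meta <- list(
    format = "tcbfstem-datacube-v1",
    dims = d, order = "column-major", dtype = "float64le",
    scan_step_A = cube$scan_step,
    det_pixel_mrad = 1e3 * cube$det_pixel,
    det_center = cube$det_center,
    kV = if (!is.null(cube$optics)) cube$optics$voltage_kv else NULL,
    alpha_mrad = if (!is.null(cube$optics)) 1e3 * cube$optics$alpha else NULL,
    dose = cube$dose, seed = cube$seed,
    provenance = cube$provenance)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(cube$counts), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a datacube container
#'
#' Inverse of [write_datacube()]. A missing sidecar or truncated payload is
#' a format error; missing calibration attributes fall back to defaults
#' with a warning.
#'
#' @param path Path written by [write_datacube()].
#' @return A [datacube4d()].
#' @export
read_datacube <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("format error: missing sidecar ", sidecar, call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("format error: missing counts payload ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$dims)) {
    stop("format error: sidecar lacks 'dims'", call. = FALSE)
  }
  d <- as.integer(meta$dims)
  n <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(vals) < n) {
    stop("format error: truncated counts payload (expected ", n,
         " values, got ", length(vals), ")", call. = FALSE)
  }
  grab <- function(name, default) {
    if (is.null(meta[[name]])) {
      warning("missing attribute '", name, "'; using default ", default)
      default
    } else meta[[name]]
  }
  scan_step <- grab("scan_step_A", 1)
  det_pixel <- grab("det_pixel_mrad", 1) * 1e-3
  det_center <- meta$det_center
  if (is.null(det_center)) {
    warning("missing attribute 'det_center'; using geometric centre")
    det_center <- c(floor(d[3] / 2), floor(d[4] / 2))
  }
  optics <- if (!is.null(meta$kV) && !is.null(meta$alpha_mrad)) {
    optical_config(meta$kV, meta$alpha_mrad * 1e-3)
  }
  datacube4d(array(vals, dim = d), scan_step, det_pixel,
             as.numeric(det_center), optics = optics,
             dose = if (is.null(meta$dose)) NA_real_ else meta$dose,
             seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
             provenance = as.list(meta$provenance))
}

# ---- MRC (mode 2, 32-bit float) -------------------------------------------

write_mrc <- function(image, path, pixel_size = 1) {
  nx <- ncol(image); ny <- nrow(image)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, 1L))                     # nx ny nz
  wi(2L)                                # mode 2 = float32
  wi(c(0L, 0L, 0L))                     # nxstart
  wi(c(nx, ny, 1L))                     # mx my mz
  wf(c(nx * pixel_size, ny * pixel_size, pixel_size))  # cella (A)
  wf(c(90, 90, 90))                     # cellb
  wi(c(1L, 2L, 3L))                     # mapc mapr maps
  wf(c(min(image), max(image), mean(image)))
  wi(c(0L, 0L))                         # ispg, nsymbt
  wi(integer(25))                       # extra
  wf(c(0, 0, 0))                        # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(image))                  # rms
  wi(0L)                                # nlabl
  writeBin(raw(800), con)               # labels
  # x fastest: write the transpose so columns (x) vary fastest on disk
  writeBin(as.numeric(t(image)), con, size = 4, endian = "little")
  invisible(path)
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_n <- readBin(con, integer(), 3, size = 4, endian = "little")
  mode <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (mode != 2) stop("unsupported MRC mode ", mode, call. = FALSE)
  readBin(con, integer(), 3, size = 4, endian = "little")   # nxstart
  m <- readBin(con, integer(), 3, size = 4, endian = "little")
  cella <- readBin(con, numeric(), 3, size = 4, endian = "little")
  seek(con, 1024)
  vals <- readBin(con, numeric(), hdr_n[1] * hdr_n[2] * hdr_n[3],
                  size = 4, endian = "little")
  img <- t(matrix(vals, hdr_n[1], hdr_n[2]))
  attr(img, "pixel_size") <- cella[1] / m[1]
  img
}

#' Write a 2-D image (MRC mode 2 or 16-bit TIFF)
#'
#' MRC stores 32-bit floats with the pixel size in the header. TIFF stores
#' 16 bits after a linear rescale to the data range; the rescale (offset,
#' scale) is recorded in a JSON sidecar so [read_image()] inverts it.
#'
#' @param image Finite numeric matrix.
#' @param path Output path; format from extension unless given.
#' @param format "mrc" or "tiff" (default: by extension).
#' @param pixel_size Pixel size (A), stored where the format allows.
#' @param sanitize How to handle non-finite pixels: "fail" or "mask"
#'   (replace by the finite minimum).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL, pixel_size = 1,
                        sanitize = c("fail", "mask")) {
  sanitize <- match.arg(sanitize)
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) {
    if (sanitize == "fail") {
      stop("image contains non-finite pixels", call. = FALSE)
    }
    image[!is.finite(image)] <- min(image[is.finite(image)])
  }
  if (is.null(format)) {
    format <- if (grepl("\\.mrc$", path, ignore.case = TRUE)) "mrc" else "tiff"
  }
  if (format == "mrc") {
    write_mrc(image, path, pixel_size)
  } else {
    lo <- min(image); hi <- max(image)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((image - lo) / scale, path, bits.per.sample = 16)
    jsonlite::write_json(
      list(offset = lo, scale = scale, pixel_size_A = pixel_size),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path MRC or TIFF path.
#' @return Matrix; MRC carries a `pixel_size` attribute, TIFF is rescaled
#'   back through its sidecar when present.
#' @export
read_image <- function(path) {
  if (grepl("\\.mrc$", path, ignore.case = TRUE)) return(read_mrc(path))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- img * meta$scale + meta$offset
    attr(img, "pixel_size") <- meta$pixel_size_A
  }
  img
}

# ---- Run configuration -----------------------------------------------------

run_config_keys <- c("subcommand", "seed", "out_dir", "log_level", "phantom",
                     "kv", "alpha_mrad", "det_pixel_mrad", "defocus_nm",
                     "scan_step_angstrom", "scan_shape", "detector_shape",
                     "dose", "inelastic_sigma_mrad", "upsample", "max_iter",
                     "edge_margin", "regularize", "mode", "omega_max_mrad",
                     "n_points", "lambda_in_nm", "a_ha", "corrected")

#' Read a run-configuration file
#'
#' YAML document mirroring the command-line flags. Unknown keys are
#' rejected, naming the offending key; the parse/serialize round trip is
#' lossless.
#'
#' @param path YAML file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write a run-configuration file
#' @param cfg Named list (validated against the known keys).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
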