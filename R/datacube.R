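#' 4D-STEM datacube
#'
#' Counts I(scan_row, scan_col, det_row, det_col) with scan-step and
#' detector-angle calibration. Detector angles are
#' Theta = (index - det_center) * det_pixel, indices 0-based.
#'
#' @param counts 4-D array of non-negative counts.
#' @param scan_step Scan step (A).
#' @param det_pixel Detector angular pixel size (rad).
#' @param det_center Fractional detector centre c(row, col), 0-based.
#' @param optics An [optical_config()] or NULL.
#' @param dose Incident dose (e-/A^2) or NA.
#' @param seed Seed used in generation, or NA.
#' @param provenance Free-form metadata list.
#' @return Object of class `datacube4d`.
#' @export
datacube4d <- function(counts, scan_step, det_pixel, det_center,
                       optics = NULL, dose = NA_real_, seed = NA_integer_,
                       provenance = list()) {
  stopifnot(length(dim(counts)) == 4, scan_step > 0, det_pixel > 0)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(counts = counts, scan_step = scan_step,
                 det_pixel = det_pixel, det_center = det_center,
                 optics = optics, dose = dose, seed = seed,
                 provenance = provenance),
            class = "datacube4d")
}

#' @export
print.datacube4d <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<datacube4d> scan %d x %d @ %g A, detector %d x %d @ %.3f mrad/px\n",
    d[1], d[2], x$scan_step, d[3], d[4], 1e3 * x$det_pixel))
  invisible(x)
}

#' @export
dim.datacube4d <- function(x) dim(x$counts)

# Detector angle grids (rad): list(theta_x, theta_y) matrices over det pixels.
detector_angles <- function(cube) {
  d <- dim(cube$counts)
  rows <- (seq_len(d[3]) - 1) - cube$det_center[1]
  cols <- (seq_len(d[4]) - 1) - cube$det_center[2]
  list(theta_y = matrix(rows * cube$det_pixel, d[3], d[4]),
       theta_x = matrix(rep(cols * cube$det_pixel, each = d[3]), d[3], d[4]))
}
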