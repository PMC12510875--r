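#' Acquisition-design report
#'
#' Derived optical and sampling quantities for planning a defocused-probe
#' acquisition:
#' \itemize{
#'   \item geometric probe blur diameter Dw = 2 alpha df
#'   \item single-detector-pixel blur delta = dalpha * df
#'   \item gap-free maximum scan step sqrt(2) alpha df and the
#'     uniform-dose recommendation alpha df
#'   \item maximum useful upsampling Dw/delta = alpha/dalpha
#'   \item depth of field 2 lambda / alpha^2
#'   \item diffraction-limited probe size 0.61 lambda / alpha
#'   \item information-limit periods lambda/alpha (1 alpha cutoff) and
#'     lambda/(2 alpha) (2 alpha cutoff)
#'   \item scan Nyquist period 2 * scan step
#' }
#'
#' @param voltage_kv Accelerating voltage (kV).
#' @param alpha Probe-forming semi-angle (rad).
#' @param delta_alpha Detector angular pixel (rad).
#' @param defocus Defocus (A).
#' @param scan_step Scan step (A).
#' @return Object of class `design_report` (a list of the quantities above,
#'   lengths in A, plus `flags` naming any sampling risks).
#' @examples
#' design_report(300, 2e-3, 0.25e-3, 1e4, 8)
#' @export
design_report <- function(voltage_kv, alpha, delta_alpha, defocus,
                          scan_step) {
  vals <- c(voltage_kv, alpha, delta_alpha, defocus, scan_step)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all design inputs must be positive and finite", call. = FALSE)
  }
  lambda <- electron_wavelength(voltage_kv)
  rep_ <- list(
    voltage_kv = voltage_kv, lambda = lambda, alpha = alpha,
    delta_alpha = delta_alpha, defocus = defocus, scan_step = scan_step,
    probe_blur_diameter = 2 * alpha * defocus,
    single_pixel_blur = delta_alpha * defocus,
    max_step_gap_free = sqrt(2) * alpha * defocus,
    recommended_step = alpha * defocus,
    max_upsampling = alpha / delta_alpha,
    depth_of_field = 2 * lambda / alpha^2,
    probe_size_diffraction = 0.61 * lambda / alpha,
    info_limit_1a = lambda / alpha,
    info_limit_2a = lambda / (2 * alpha),
    scan_nyquist_period = 2 * scan_step)
  flags <- character()
  if (scan_step > rep_$max_step_gap_free) flags <- c(flags, "gap_risk")
  if (scan_step > rep_$recommended_step) flags <- c(flags, "nonuniform_dose")
  rep_$flags <- flags
  structure(rep_, class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %g kV, alpha %.2f mrad, defocus %g nm\n",
              x$voltage_kv, 1e3 * x$alpha, x$defocus / 10))
  cat(sprintf("  probe blur 2*alpha*df       : %.1f nm\n",
              x$probe_blur_diameter / 10))
  cat(sprintf("  pixel blur dalpha*df        : %.2f A\n", x$single_pixel_blur))
  cat(sprintf("  gap-free max step           : %.1f A\n", x$max_step_gap_free))
  cat(sprintf("  uniform-dose step           : <= %.1f A\n", x$recommended_step))
  cat(sprintf("  max useful upsampling       : %.1f\n", x$max_upsampling))
  cat(sprintf("  depth of field 2L/a^2       : %.1f nm\n", x$depth_of_field / 10))
  cat(sprintf("  probe size 0.61L/a          : %.2f A\n",
              x$probe_size_diffraction))
  cat(sprintf("  info limit (1a / 2a)        : %.2f / %.2f A\n",
              x$info_limit_1a, x$info_limit_2a))
  cat(sprintf("  scan Nyquist period         : %.1f A\n",
              x$scan_nyquist_period))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Acquisition speed-up from upsampling
#'
#' The areal acquisition speed-up from sampling at `scan_step` instead of
#' at half the achieved resolution: the linear ratio
#' 2 * scan_step / achieved_resolution is rounded to the nearest integer
#' and squared (a step of 8 A with 2.3 A achieved resolution gives a
#' linear factor 7 and an areal factor 49).
#'
#' @param scan_step Scan step (A).
#' @param achieved_resolution Achieved resolution (A).
#' @return List with `linear` and `areal` factors.
#' @export
speedup_factor <- function(scan_step, achieved_resolution) {
  stopifnot(scan_step > 0, achieved_resolution > 0)
  lin <- round(2 * scan_step / achieved_resolution)
  list(linear = lin, areal = lin^2)
}
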