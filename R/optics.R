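#' Relativistic electron wavelength
#'
#' Wavelength of an electron accelerated through `voltage_kv` kilovolts,
#' from the relativistic de Broglie relation with CODATA 2018 constants.
#'
#' @param voltage_kv Accelerating voltage in kV (scalar or vector, > 0).
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(300)  # 0.019687 A
#' @export
electron_wavelength <- function(voltage_kv) {
  if (any(!is.finite(voltage_kv)) || any(voltage_kv <= 0)) {
    stop("voltage_kv must be positive and finite", call. = FALSE)
  }
  h  <- 6.62607015e-34   # Planck constant, J s
  m0 <- 9.1093837015e-31 # electron rest mass, kg
  e  <- 1.602176634e-19  # elementary charge, C
  c0 <- 2.99792458e8     # speed of light, m/s
  V <- voltage_kv * 1e3
  lam_m <- h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * c0^2)))
  lam_m * 1e10
}

#' Electron-optical configuration
#'
#' Bundles the accelerating voltage, derived wavelength and wavenumber, the
#' probe-forming aperture semi-angle alpha, and the detector angular pixel
#' size. All angles are in radians, lengths in Angstrom.
#'
#' @param voltage_kv Accelerating voltage (kV).
#' @param alpha Probe-forming aperture semi-angle (rad).
#' @param delta_alpha Detector angular pixel size (rad), optional; must be
#'   smaller than `alpha` when given.
#' @return An object of class `optical_config` with fields `voltage_kv`,
#'   `lambda` (A), `k0` (rad/A), `alpha`, `delta_alpha`, `omega0` (sr).
#' @examples
#' cfg <- optical_config(300, alpha = 5.5e-3)
#' cfg$lambda
#' @export
optical_config <- function(voltage_kv, alpha, delta_alpha = NULL) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.null(delta_alpha)) {
    if (!is.finite(delta_alpha) || delta_alpha <= 0) {
      stop("delta_alpha must be > 0", call. = FALSE)
    }
    if (delta_alpha >= alpha) stop("delta_alpha must be < alpha", call. = FALSE)
  }
  lambda <- electron_wavelength(voltage_kv)
  structure(
    list(voltage_kv = voltage_kv, lambda = lambda, k0 = 2 * pi / lambda,
         alpha = alpha, delta_alpha = delta_alpha, omega0 = pi * alpha^2),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> %g kV  lambda = %.6f A  alpha = %.3f mrad",
              x$voltage_kv, x$lambda, 1e3 * x$alpha))
  if (!is.null(x$delta_alpha)) {
    cat(sprintf("  delta_alpha = %.3f mrad", 1e3 * x$delta_alpha))
  }
  cat("\n")
  invisible(x)
}

#' Aberration surface of the probe-forming lens
#'
#' Parameters of the aberration phase chi(Theta). With only defocus set,
#' chi(Theta) = -1/2 k0 df |Theta|^2; astigmatism adds
#' -1/2 k0 A1 |Theta|^2 cos 2(phi - phi_A) and third-order spherical
#' aberration adds -1/4 k0 C3 |Theta|^4 (signs consistent with the defocus
#' term, so positive defocus produces outward parallax shifts W = df Theta).
#'
#' @param defocus Defocus df in Angstrom.
#' @param astig_mag,astig_angle Twofold astigmatism magnitude (A) and
#'   azimuth (rad).
#' @param c3 Third-order spherical aberration coefficient (A).
#' @return An object of class `aberration_surface`.
#' @export
aberration_surface <- function(defocus = 0, astig_mag = 0, astig_angle = 0,
                               c3 = 0) {
  stopifnot(is.finite(defocus), is.finite(astig_mag), is.finite(astig_angle),
            is.finite(c3))
  structure(list(defocus = defocus, astig_mag = astig_mag,
                 astig_angle = astig_angle, c3 = c3),
            class = "aberration_surface")
}

#' @export
print.aberration_surface <- function(x, ...) {
  cat(sprintf("<aberration_surface> defocus = %g A", x$defocus))
  if (x$astig_mag != 0) {
    cat(sprintf("  A1 = %g A @ %.1f deg", x$astig_mag,
                x$astig_angle * 180 / pi))
  }
  if (x$c3 != 0) cat(sprintf("  C3 = %g A", x$c3))
  cat("\n")
  invisible(x)
}

# Coerce angle input to an n x 2 matrix (theta_x, theta_y).
as_theta_matrix <- function(theta) {
  if (is.matrix(theta)) {
    if (ncol(theta) != 2) stop("theta must have two columns", call. = FALSE)
    theta
  } else {
    if (length(theta) != 2) stop("theta must be a 2-vector", call. = FALSE)
    matrix(theta, ncol = 2)
  }
}

#' Aberration phase chi(Theta)
#'
#' @param ab An [aberration_surface()].
#' @param cfg An [optical_config()] supplying the wavenumber k0.
#' @param theta Angle 2-vector or n x 2 matrix (rad).
#' @return Phase in radians (vector of length n).
#' @examples
#' cfg <- optical_config(300, 5.5e-3)
#' chi(aberration_surface(defocus = 1e4), cfg, c(5e-3, 0))  # -39.89 rad
#' @export
chi <- function(ab, cfg, theta) {
  th <- as_theta_matrix(theta)
  if (any(!is.finite(th))) stop("theta must be finite", call. = FALSE)
  t2 <- th[, 1]^2 + th[, 2]^2
  val <- -0.5 * cfg$k0 * ab$defocus * t2
  if (ab$astig_mag != 0) {
    phi <- atan2(th[, 2], th[, 1])
    val <- val - 0.5 * cfg$k0 * ab$astig_mag * t2 *
      cos(2 * (phi - ab$astig_angle))
  }
  if (ab$c3 != 0) val <- val - 0.25 * cfg$k0 * ab$c3 * t2^2
  val
}

#' Aperture indicator A(Theta)
#'
#' 1 inside the probe-forming aperture (|Theta| <= alpha), 0 outside.
#'
#' @inheritParams chi
#' @return Numeric vector of 0/1.
#' @export
aperture <- function(cfg, theta) {
  th <- as_theta_matrix(theta)
  as.numeric(sqrt(th[, 1]^2 + th[, 2]^2) <= cfg$alpha)
}

#' Transfer curve container
#'
#' A radial transfer curve: scattering-angle magnitudes omega (rad), the
#' corresponding (possibly complex) transfer values, and a mode label.
#' Spatial frequency is obtained as q = omega / lambda at I/O boundaries.
#'
#' @param omega Scattering-angle magnitudes (rad).
#' @param values Transfer values.
#' @param label One of "axial_bf", "tilted", "tcbf", "dpc", "idpc",
#'   "dqe_tcbf", "dqe_dpc", "dqe_idpc", or similar mode tag.
#' @return Object of class `transfer_curve`.
#' @export
transfer_curve <- function(omega, values, label) {
  stopifnot(length(omega) == length(values))
  structure(list(omega = omega, values = values, label = label),
            class = "transfer_curve")
}

#' @export
print.transfer_curve <- function(x, ...) {
  cat(sprintf("<transfer_curve '%s'> %d points, omega in [%g, %g] mrad\n",
              x$label, length(x$omega), 1e3 * min(x$omega),
              1e3 * max(x$omega)))
  invisible(x)
}

#' @export
as.data.frame.transfer_curve <- function(x, ..., lambda = NULL) {
  d <- data.frame(omega_mrad = 1e3 * x$omega, value = x$values)
  if (!is.null(lambda)) d$q_inv_angstrom <- x$omega / lambda
  d
}

#' Tilted-beam phase-contrast transfer function
#'
#' PCTF for the image formed by a single detector pixel at tilt `theta`
#' inside the bright-field disk:
#' \deqn{(i/2) A(\Theta)\{A(\omega-\Theta) e^{-i[\chi(\omega-\Theta)-\chi(\Theta)]}
#'   - A(\omega+\Theta) e^{+i[\chi(\omega+\Theta)-\chi(\Theta)]}\}}
#' The solid-angle prefactor is absorbed into the factor 1/2 so that
#' |PCTF| <= 1. At `theta = 0` the curve is purely real and reduces to the
#' axial bright-field CTF sin(chi(omega)) with cutoff at alpha; for
#' |theta| = alpha the support extends to 2 alpha.
#'
#' @param cfg An [optical_config()].
#' @param ab An [aberration_surface()].
#' @param omega_grid n x 2 matrix (or 2-vector) of image spatial-frequency
#'   angles omega (rad).
#' @param theta Detector tilt 2-vector (rad), |theta| <= alpha.
#' @return Complex vector of transfer values.
#' @export
pctf_tilted <- function(cfg, ab, omega_grid, theta) {
  th <- as_theta_matrix(theta)
  if (sqrt(sum(th[1, ]^2)) > cfg$alpha + 1e-12) {
    stop("invalid tilt: |theta| exceeds the aperture semi-angle alpha",
         call. = FALSE)
  }
  om <- as_theta_matrix(omega_grid)
  a_th <- aperture(cfg, th)
  om_m <- sweep(om, 2, th[1, ], `-`)
  om_p <- sweep(om, 2, th[1, ], `+`)
  chi_th <- chi(ab, cfg, th)
  term1 <- aperture(cfg, om_m) * exp(-1i * (chi(ab, cfg, om_m) - chi_th))
  term2 <- aperture(cfg, om_p) * exp(+1i * (chi(ab, cfg, om_p) - chi_th))
  (1i / 2) * a_th * (term1 - term2)
}

#' Axial bright-field CTF
#'
#' The theta = 0 limit of [pctf_tilted()]: sin(chi(omega)) with support
#' |omega| <= alpha. For pure defocus this is -sin(1/2 k0 df omega^2).
#'
#' @inheritParams ctf_tcbf
#' @return A [transfer_curve()] labelled "axial_bf".
#' @export
ctf_axial_bf <- function(cfg, defocus, omega) {
  stopifnot(all(omega >= 0))
  ab <- aberration_surface(defocus = defocus)
  v <- sin(chi(ab, cfg, cbind(omega, 0))) * as.numeric(omega <= cfg$alpha)
  transfer_curve(omega, v, "axial_bf")
}

#' Disk-overlap damping envelope
#'
#' Normalized overlap area of two disks of radius alpha whose centres are
#' u * alpha apart:
#' \deqn{L(u) = (2/\pi)[\cos^{-1}(u/2) - (u/2)\sqrt{1-u^2/4}]}
#' for 0 <= u <= 2 and 0 beyond. L is the familiar self-luminous (ADF)
#' envelope; it damps the tcBF CTF and is the shape of the iDPC curve.
#'
#' @param u Dimensionless ratio omega/alpha (>= 0).
#' @return Envelope values in [0, 1].
#' @examples
#' overlap_envelope(c(0, 1, 2))  # 1, 0.3910, 0
#' @export
overlap_envelope <- function(u) {
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("u must be finite and >= 0", call. = FALSE)
  }
  out <- numeric(length(u))
  inside <- u < 2
  ui <- u[inside]
  out[inside] <- (2 / pi) * (acos(ui / 2) - (ui / 2) * sqrt(1 - ui^2 / 4))
  out
}

#' Closed-form tcBF contrast transfer function
#'
#' The tilt-corrected bright-field CTF obtained by summing the
#' tilt-corrected single-pixel PCTFs over the full bright-field disk:
#' \deqn{CTF_{tcBF}(\omega) = -L(\omega/\alpha)\,\sin(\tfrac12 k_0 \Delta f\, \omega^2)}
#' with support |omega| <= 2 alpha. Shares its zero crossings with the
#' axial bright-field CTF inside (0, alpha].
#'
#' @param cfg An [optical_config()].
#' @param defocus Defocus (A).
#' @param omega Scattering-angle magnitudes (rad, >= 0).
#' @return A [transfer_curve()] labelled "tcbf".
#' @export
ctf_tcbf <- function(cfg, defocus, omega) {
  stopifnot(all(omega >= 0))
  v <- -overlap_envelope(omega / cfg$alpha) *
    sin(0.5 * cfg$k0 * defocus * omega^2)
  transfer_curve(omega, v, "tcbf")
}

# Antialiased indicator of |p - center| <= alpha for quadrature cells of
# linear size h: fraction of the cell inside the disk, linearized at the rim.
aa_disk <- function(dist, alpha, h) {
  pmin(pmax(0.5 + (alpha - dist) / h, 0), 1)
}

#' Numeric half-disk tcBF CTF (quadrature oracle)
#'
#' Sums the symmetric tilt pairs of the tilted PCTF over half of the
#' bright-field disk on a uniform Cartesian grid, with rim cells weighted
#' by their fractional area. For defocus-only aberrations this converges
#' to the closed form [ctf_tcbf()]; agreement is better than 1e-3 at the
#' default resolution.
#'
#' @inheritParams ctf_tcbf
#' @param ab An [aberration_surface()]; only the defocus term enters the
#'   paired-sum kernel (the pair sum cancels odd aberrations).
#' @param n_samples Grid samples across the disk diameter (>= 64).
#' @return A [transfer_curve()] labelled "tcbf_numeric".
#' @export
ctf_tcbf_numeric <- function(cfg, ab, omega, n_samples = 256) {
  stopifnot(all(omega >= 0))
  if (n_samples < 64) stop("n_samples must be >= 64", call. = FALSE)
  alpha <- cfg$alpha
  h <- 2 * alpha / n_samples
  xs <- seq(h / 2, alpha, by = h)          # half disk: theta_x > 0
  ys <- seq(-alpha + h / 2, alpha, by = h)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  w_ap <- aa_disk(sqrt(gx^2 + gy^2), alpha, h)
  keep <- w_ap > 0
  gx <- gx[keep]; gy <- gy[keep]; w_ap <- w_ap[keep]
  vals <- vapply(omega, function(om) {
    wm <- aa_disk(sqrt((gx - om)^2 + gy^2), alpha, h)
    wp <- aa_disk(sqrt((gx + om)^2 + gy^2), alpha, h)
    sum(w_ap * (wm + wp)) * h^2
  }, numeric(1))
  v <- -(vals / (pi * alpha^2)) * sin(0.5 * cfg$k0 * ab$defocus * omega^2)
  transfer_curve(omega, v, "tcbf_numeric")
}

#' In-focus DPC contrast transfer function
#'
#' Radial CTF of the differential phase-contrast signal built by combining
#' the in-focus single-pixel PCTFs over detector half planes with
#' first-moment (tilt-proportional, centre-of-mass) weighting. The closed
#' form is 2 (omega/alpha) L(omega/alpha); [ctf_dpc_numeric()] integrates
#' the half-plane moment directly. Support ends at 2 alpha and the curve
#' is zero at omega = 0.
#'
#' @param cfg An [optical_config()].
#' @param omega Scattering-angle magnitudes (rad, >= 0).
#' @return A [transfer_curve()] labelled "dpc".
#' @export
ctf_dpc <- function(cfg, omega) {
  stopifnot(all(omega >= 0))
  u <- omega / cfg$alpha
  transfer_curve(omega, 2 * u * overlap_envelope(u), "dpc")
}

#' Numeric DPC CTF by half-plane moment quadrature
#'
#' Direct grid integration of the tilt-weighted half-plane difference of
#' the in-focus single-pixel PCTF; independent oracle for [ctf_dpc()].
#'
#' @inheritParams ctf_dpc
#' @param n_samples Grid samples across the disk diameter.
#' @return A [transfer_curve()] labelled "dpc_numeric".
#' @export
ctf_dpc_numeric <- function(cfg, omega, n_samples = 256) {
  stopifnot(all(omega >= 0))
  alpha <- cfg$alpha
  h <- 2 * alpha / n_samples
  xs <- seq(-alpha + h / 2, alpha, by = h)
  gx <- rep(xs, times = length(xs))
  gy <- rep(xs, each = length(xs))
  w_ap <- aa_disk(sqrt(gx^2 + gy^2), alpha, h)
  keep <- w_ap > 0
  gx <- gx[keep]; gy <- gy[keep]; w_ap <- w_ap[keep]
  vals <- vapply(omega, function(om) {
    wm <- aa_disk(sqrt((gx - om)^2 + gy^2), alpha, h)
    wp <- aa_disk(sqrt((gx + om)^2 + gy^2), alpha, h)
    # tilt-weighted difference of the +/- disk terms; odd kernel in theta_x
    sum(w_ap * gx * (wm - wp)) * h^2
  }, numeric(1))
  transfer_curve(omega, 2 * vals / (pi * alpha^3), "dpc_numeric")
}

#' iDPC contrast transfer function
#'
#' Integrated-DPC radial curve, the DPC curve divided by spatial frequency:
#' equal to the overlap envelope L(omega/alpha). The omega = 0 value is the
#' finite omega -> 0+ limit (1); in image-space computation the DC bin of
#' the Fourier division is excluded instead.
#'
#' @inheritParams ctf_dpc
#' @return A [transfer_curve()] labelled "idpc".
#' @export
pctf_idpc <- function(cfg, omega) {
  stopifnot(all(omega >= 0))
  transfer_curve(omega, overlap_envelope(omega / cfg$alpha), "idpc")
}

#' Overlap-region classification on the detector
#'
#' For image frequency `omega`, a detector point `theta` inside the
#' bright-field disk lies in the triple-overlap region when both diffracted
#' disks at +/- omega also cover it (phase contrast activated by defocus),
#' in the double-overlap region when exactly one does (DPC/SSB contrast),
#' and in neither otherwise.
#'
#' @param cfg An [optical_config()].
#' @param omega Image-frequency angle 2-vector (rad).
#' @param theta Detector angle 2-vector (rad), |theta| <= alpha.
#' @return One of "none", "double", "triple".
#' @export
overlap_region <- function(cfg, omega, theta) {
  om <- as_theta_matrix(omega)[1, ]
  th <- as_theta_matrix(theta)[1, ]
  if (sqrt(sum(th^2)) > cfg$alpha + 1e-12) {
    stop("invalid tilt: |theta| exceeds alpha", call. = FALSE)
  }
  n_cover <- (sqrt(sum((th - om)^2)) < cfg$alpha) +
    (sqrt(sum((th + om)^2)) < cfg$alpha)
  c("none", "double", "triple")[n_cover + 1L]
}

#' Detective quantum efficiency curves
#'
#' Frequency-resolved dose efficiency for tcBF, DPC and iDPC under a noise
#' power spectrum normalized to 1 (ideal-pixel convention DQE(0) = 1 for a
#' perfect transfer). With flat unit noise each DQE is the squared CTF:
#' DQE_tcbf = |CTF_tcbf|^2, DQE_dpc = |CTF_dpc|^2, and the iDPC DQE is the
#' two-component average of the DPC DQEs, which for the radial curve equals
#' the DPC DQE (noise is amplified by the same 1/omega integration as the
#' signal).
#'
#' @param cfg An [optical_config()].
#' @param defocus Defocus (A), used by the tcBF branch.
#' @param omega Scattering-angle magnitudes (rad, >= 0).
#' @param nps Noise power spectrum, scalar 1 or a vector over `omega`.
#' @return Named list of [transfer_curve()]s: `dqe_tcbf`, `dqe_dpc`,
#'   `dqe_idpc`.
#' @export
dqe_curves <- function(cfg, defocus, omega, nps = 1) {
  stopifnot(all(omega >= 0), all(nps > 0))
  tc <- ctf_tcbf(cfg, defocus, omega)$values
  dp <- ctf_dpc(cfg, omega)$values
  list(
    dqe_tcbf = transfer_curve(omega, Mod(tc)^2 / nps^2, "dqe_tcbf"),
    dqe_dpc  = transfer_curve(omega, Mod(dp)^2 / nps^2, "dqe_dpc"),
    # Eq-style two-component average with equal x/y components
    dqe_idpc = transfer_curve(omega, (Mod(dp)^2 + Mod(dp)^2) / (2 * nps^2),
                              "dqe_idpc"))
}

#' Thickness-averaged tcBF CTF
#'
#' Approximates the effective CTF of a sample that is uniform through its
#' thickness by averaging the tcBF CTF over defocus values spanning
#' `thickness` around `defocus_center`. High frequencies damp out roughly
#' on the depth-of-field scale dz ~ lambda/omega^2 per spatial frequency.
#'
#' @param cfg An [optical_config()].
#' @param defocus_center Central defocus (A).
#' @param thickness Sample thickness (A, >= 0).
#' @param omega Scattering-angle magnitudes (rad).
#' @param n_slices Number of defocus samples in the average.
#' @return A [transfer_curve()] labelled "tcbf_thickness_avg".
#' @export
ctf_thickness_averaged <- function(cfg, defocus_center, thickness, omega,
                                   n_slices = 65) {
  stopifnot(thickness >= 0, n_slices >= 1)
  if (thickness == 0 || n_slices == 1) {
    out <- ctf_tcbf(cfg, defocus_center, omega)
    out$label <- "tcbf_thickness_avg"
    return(out)
  }
  dfs <- seq(defocus_center - thickness / 2, defocus_center + thickness / 2,
             length.out = n_slices)
  acc <- Reduce(`+`, lapply(dfs, function(df) ctf_tcbf(cfg, df, omega)$values))
  transfer_curve(omega, acc / n_slices, "tcbf_thickness_avg")
}
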