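#' Weak-phase object
#'
#' A projected specimen for the single-slice forward model: a phase map
#' (rad), an amplitude map in [0, 1], the real-space pixel size (A) and an
#' optional thickness (nm) driving attenuation and inelastic blur.
#'
#' @param phase Matrix of projected phase (rad).
#' @param amplitude Matrix in [0, 1] or scalar 1.
#' @param pixel_size Pixel size (A, > 0).
#' @param thickness Scalar thickness (nm) or NULL.
#' @return Object of class `weak_phase_object`.
#' @export
weak_phase_object <- function(phase, amplitude = 1, pixel_size,
                              thickness = NULL) {
  stopifnot(is.matrix(phase), all(is.finite(phase)), pixel_size > 0)
  if (is.matrix(amplitude)) {
    stopifnot(all(dim(amplitude) == dim(phase)))
  } else {
    amplitude <- matrix(amplitude, nrow(phase), ncol(phase))
  }
  if (any(amplitude < 0 | amplitude > 1)) {
    stop("amplitude must lie in [0, 1]", call. = FALSE)
  }
  structure(list(phase = phase, amplitude = amplitude,
                 pixel_size = pixel_size, thickness = thickness),
            class = "weak_phase_object")
}

#' @export
print.weak_phase_object <- function(x, ...) {
  cat(sprintf("<weak_phase_object> %d x %d px @ %g A, phase range [%.3f, %.3f] rad\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size,
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' Synthetic test phantoms
#'
#' Generates weak/strong-phase phantoms emulating common test specimens:
#' \describe{
#'   \item{gold_on_carbon}{Strong-phase disks on a low-amplitude smooth
#'     background; each disk carries a sinusoidal lattice at `lattice_spacing`
#'     with a random orientation, so the power spectrum shows a ring at
#'     1/spacing.}
#'   \item{membranes}{Paired parallel Gaussian ridges (bilayers) at
#'     `separation`, at random positions and orientations.}
#'   \item{point_grid}{Sparse Gaussian bumps on a regular grid (or a single
#'     centred bump when `n_points = 1`).}
#' }
#' Deterministic for a given `seed`.
#'
#' @param kind One of "gold_on_carbon", "membranes", "point_grid".
#' @param size Side length in pixels (>= 64).
#' @param pixel_size Pixel size (A).
#' @param params Optional list overriding kind-specific defaults:
#'   `n_disks`, `disk_radius_A`, `disk_phase`, `lattice_spacing`
#'   (A, gold_on_carbon); `n_pairs`, `separation`, `ridge_sigma`,
#'   `ridge_phase` (membranes); `n_points`, `sigma_A`, `amplitude`
#'   (point_grid); `background_rms` (all kinds).
#' @param seed Integer seed.
#' @return A [weak_phase_object()].
#' @export
make_phantom <- function(kind = c("gold_on_carbon", "membranes", "point_grid"),
                         size = 256, pixel_size = 1, params = list(),
                         seed = 1) {
  kind <- match.arg(kind)
  if (size < 64) stop("size must be >= 64 px per side", call. = FALSE)
  set.seed(seed)
  n <- size
  xs <- (seq_len(n) - 1) * pixel_size
  X <- matrix(rep(xs, each = n), n, n)   # column coordinate (x)
  Y <- matrix(rep(xs, times = n), n, n)  # row coordinate (y)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default

  bg_rms <- p("background_rms", 0.02)
  bg_sigma <- p("background_sigma_A", 3 * pixel_size)
  phase <- matrix(stats::rnorm(n * n), n, n)
  phase <- gauss_blur2(phase, bg_sigma / pixel_size)
  phase <- phase / stats::sd(phase) * bg_rms

  if (kind == "gold_on_carbon") {
    n_disks <- p("n_disks", 12)
    rad <- p("disk_radius_A", 12 * pixel_size)
    dphase <- p("disk_phase", 1.0)
    s_lat <- p("lattice_spacing", max(2.3, 4.6 * pixel_size))
    if (s_lat < 2 * pixel_size) {
      stop("aliasing: lattice_spacing below 2 * pixel_size", call. = FALSE)
    }
    a_lat <- p("lattice_amplitude", 0.3)
    edge_sig <- p("disk_edge_sigma_A", 0)
    disks <- matrix(0, n, n); lattice <- matrix(0, n, n)
    for (i in seq_len(n_disks)) {
      cx <- stats::runif(1, 0, n * pixel_size)
      cy <- stats::runif(1, 0, n * pixel_size)
      r <- rad * stats::runif(1, 0.7, 1.3)
      # periodic distances so disks wrap cleanly
      dxp <- abs(X - cx); dxp <- pmin(dxp, n * pixel_size - dxp)
      dyp <- abs(Y - cy); dyp <- pmin(dyp, n * pixel_size - dyp)
      m <- dxp^2 + dyp^2 <= r^2
      ang <- stats::runif(1, 0, pi)
      lat <- a_lat * sin(2 * pi * (cos(ang) * X + sin(ang) * Y) / s_lat)
      disks[m] <- disks[m] + dphase * stats::runif(1, 0.6, 1.2)
      lattice[m] <- lattice[m] + lat[m]
    }
    # rim softening applies to the disk envelope only; the lattice stays sharp
    if (edge_sig > 0) disks <- gauss_blur2(disks, edge_sig / pixel_size)
    phase <- phase + disks + lattice
    # optional absorption channel: strong scatterers lose intensity to
    # angles outside the collection aperture, giving in-focus amplitude
    # contrast (a pure weak-phase object is invisible at exact focus)
    ac <- p("amplitude_contrast", 0)
    if (ac > 0 && max(disks) > 0) {
      amplitude <- exp(-ac * pmax(disks, 0) / max(disks))
      return(weak_phase_object(phase, amplitude, pixel_size))
    }
  } else if (kind == "membranes") {
    n_pairs <- p("n_pairs", 4)
    sep <- p("separation", 40 * pixel_size)
    sig <- p("ridge_sigma", 2 * pixel_size)
    rphase <- p("ridge_phase", 0.5)
    for (i in seq_len(n_pairs)) {
      ang <- stats::runif(1, 0, pi)
      off <- stats::runif(1, 0.2, 0.8) * n * pixel_size
      u <- cos(ang) * X + sin(ang) * Y
      for (d in c(-sep / 2, sep / 2)) {
        phase <- phase + rphase * exp(-((u - off - d)^2) / (2 * sig^2))
      }
    }
  } else { # point_grid
    n_points <- p("n_points", 9)
    sig <- p("sigma_A", 2 * pixel_size)
    amp <- p("amplitude", 1.0)
    if (n_points == 1) {
      centers <- matrix(c(n, n) / 2 * pixel_size, 1, 2)
    } else {
      k <- ceiling(sqrt(n_points))
      g <- (seq_len(k) - 0.5) / k * n * pixel_size
      centers <- as.matrix(expand.grid(g, g))[seq_len(n_points), , drop = FALSE]
    }
    for (i in seq_len(nrow(centers))) {
      phase <- phase + amp *
        exp(-((X - centers[i, 1])^2 + (Y - centers[i, 2])^2) / (2 * sig^2))
    }
  }
  weak_phase_object(phase, 1, pixel_size)
}

#' Aberrated probe wavefunction
#'
#' Real-space probe from the aperture and aberration phase:
#' psi = IFFT[A(Theta) exp(-i chi(Theta))], normalized to unit total
#' intensity. At zero defocus this is an Airy-like spot with first zero at
#' about 0.61 lambda / alpha; at large defocus the intensity fills the
#' geometric disk of diameter 2 alpha |df|.
#'
#' @param cfg An [optical_config()].
#' @param ab An [aberration_surface()].
#' @param field_size Field side length (px).
#' @param pixel_size Pixel size (A).
#' @return Complex matrix (field_size x field_size), DC-centred probe.
#' @export
build_probe <- function(cfg, ab, field_size, pixel_size) {
  blur <- 2 * cfg$alpha * abs(ab$defocus)
  if (blur > 0.9 * field_size * pixel_size) {
    stop("truncation: geometric blur disk 2*alpha*defocus exceeds the field",
         call. = FALSE)
  }
  n <- field_size
  f <- fft_freq(n, d = pixel_size)      # cycles/A, fft order
  ty <- cfg$lambda * outer(f, rep(1, n))
  tx <- cfg$lambda * outer(rep(1, n), f)
  th <- cbind(as.vector(tx), as.vector(ty))
  A <- matrix(aperture(cfg, th), n, n)
  phase <- matrix(chi(ab, cfg, th), n, n)
  psi <- ifft2(A * exp(-1i * phase))
  psi <- fftshift2(psi)                  # centre the probe in the field
  psi / sqrt(sum(Mod(psi)^2))
}

#' Simulation configuration
#'
#' Bundles everything [simulate_datacube()] needs. The scan step must be an
#' integer multiple of the phantom pixel size; the detector grid is a
#' box-binned central crop of the phantom's reciprocal grid, so the
#' detector pixel size is b * lambda / (N * pixel_size) with b the binning
#' factor.
#'
#' @param optics An [optical_config()].
#' @param aberrations An [aberration_surface()].
#' @param scan_shape c(rows, cols) of scan positions.
#' @param scan_step Scan step (A).
#' @param detector_shape c(rows, cols) of detector pixels.
#' @param dose Incident dose (e-/A^2); `Inf` disables Poisson noise.
#' @param inelastic_blur_sigma Angular blur of the inelastic channel (rad).
#' @param attenuation An [mfp_model()] or NULL; with a NULL model the
#'   specimen is treated as fully transparent apart from its own
#'   amplitude map.
#' @param preserved_contrast Fraction of elastic contrast preserved in the
#'   inelastic channel, in [0, 1].
#' @param seed Integer seed for the Poisson streams.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(optics, aberrations = aberration_surface(),
                       scan_shape = c(32, 32), scan_step = 8,
                       detector_shape = c(48, 48), dose = Inf,
                       inelastic_blur_sigma = 0, attenuation = NULL,
                       preserved_contrast = 1, seed = 1) {
  stopifnot(dose >= 0, scan_step > 0, all(scan_shape >= 1),
            all(detector_shape >= 2), inelastic_blur_sigma >= 0,
            preserved_contrast >= 0, preserved_contrast <= 1)
  structure(list(optics = optics, aberrations = aberrations,
                 scan_shape = scan_shape, scan_step = scan_step,
                 detector_shape = detector_shape, dose = dose,
                 inelastic_blur_sigma = inelastic_blur_sigma,
                 attenuation = attenuation,
                 preserved_contrast = preserved_contrast, seed = seed),
            class = "sim_config")
}

#' Simulate a defocused-probe 4D-STEM datacube
#'
#' Single-slice forward model: for every scan position R the exit wave is
#' probe(r - R) * a(r) exp(i phi(r)); the recorded pattern is the squared
#' modulus of its Fourier transform, box-binned to the detector grid. With
#' an attenuation model and a specimen thickness, the coherent pattern is
#' scaled by exp(-t/lambda_el) and a fraction 1 - exp(-t/lambda_in) is
#' redistributed through a Gaussian angular blur. Finite dose draws Poisson
#' counts from one per-position stream derived from (seed, scan index), so
#' patterns are reproducible independent of iteration order.
#'
#' @param obj A [weak_phase_object()].
#' @param sim A [sim_config()].
#' @return A [datacube4d()].
#' @export
simulate_datacube <- function(obj, sim) {
  cfg <- sim$optics
  n <- nrow(obj$phase)
  p <- obj$pixel_size
  step_px <- sim$scan_step / p
  if (abs(step_px - round(step_px)) > 1e-9) {
    stop("scan_step must be an integer multiple of the phantom pixel size",
         call. = FALSE)
  }
  step_px <- as.integer(round(step_px))
  dN <- sim$detector_shape
  b <- min(n %/% dN[1], n %/% dN[2])
  if (b < 1) stop("detector_shape exceeds the phantom reciprocal grid",
                  call. = FALSE)
  d_theta_grid <- cfg$lambda / (n * p)
  det_pixel <- b * d_theta_grid
  half_range <- dN[1] / 2 * det_pixel
  if (half_range < cfg$alpha) {
    warning("aperture clipped: detector angular range < alpha")
  } else if (half_range < 2 * cfg$alpha) {
    warning("detector angular range < 2*alpha; dark-field cut off")
  }

  probe <- build_probe(cfg, sim$aberrations, n, p)
  trans <- obj$amplitude * exp(1i * obj$phase)

  # crop window on the fftshifted reciprocal grid, centred on DC
  c0 <- floor(n / 2)                    # 0-based DC index after fftshift
  r0 <- c0 - b * floor(dN[1] / 2)       # 0-based crop start (rows)
  s0 <- c0 - b * floor(dN[2] / 2)
  if (r0 < 0 || s0 < 0 || r0 + b * dN[1] > n || s0 + b * dN[2] > n) {
    stop("detector crop exceeds reciprocal grid; reduce detector_shape",
         call. = FALSE)
  }
  # fractional (0-based) detector pixel holding DC, pixel-centre convention
  det_center <- c((c0 - r0 - (b - 1) / 2) / b, (c0 - s0 - (b - 1) / 2) / b)

  # attenuation bookkeeping
  t_nm <- if (!is.null(obj$thickness)) obj$thickness else 0
  att <- sim$attenuation
  f_el <- 1; f_inel <- 0
  if (!is.null(att) && t_nm > 0) {
    if (is.null(att$lambda_el)) {
      stop("attenuation model must include lambda_el", call. = FALSE)
    }
    f_el <- exp(-t_nm / att$lambda_el)
    f_inel <- (1 - exp(-t_nm / att$lambda_in))
  }
  blur_px <- sim$inelastic_blur_sigma / d_theta_grid

  e_per_pos <- sim$dose * sim$scan_step^2
  counts <- array(0, dim = c(sim$scan_shape, dN))
  idx <- 0L
  for (iy in seq_len(sim$scan_shape[1])) {
    for (ix in seq_len(sim$scan_shape[2])) {
      idx <- idx + 1L
      shifted <- roll2(probe, (iy - 1L) * step_px, (ix - 1L) * step_px)
      # Parseval: unit-intensity exit wave -> pattern summing to <= 1
      cbed <- Mod(fftshift2(fft2(shifted * trans)))^2 / length(trans)
      if (f_inel > 0) {
        inel <- gauss_blur2(cbed, blur_px)
        if (sim$preserved_contrast < 1) {
          flat <- gauss_blur2(cbed, max(blur_px, 4) * 4)
          inel <- sim$preserved_contrast * inel +
            (1 - sim$preserved_contrast) * flat
        }
        cbed <- f_el * cbed + f_inel * inel
      } else if (f_el < 1) {
        cbed <- f_el * cbed
      }
      pat <- bin2(cbed[r0 + seq_len(b * dN[1]), s0 + seq_len(b * dN[2])], b)
      if (is.finite(sim$dose)) {
        set.seed((sim$seed * 7919L + idx) %% .Machine$integer.max)
        pat <- matrix(stats::rpois(length(pat), pmax(pat, 0) * e_per_pos),
                      dN[1], dN[2])
      } else {
        pat <- pat * if (is.finite(e_per_pos)) e_per_pos else 1
      }
      counts[iy, ix, , ] <- pat
    }
  }
  datacube4d(counts, sim$scan_step, det_pixel, det_center, optics = cfg,
             dose = sim$dose, seed = sim$seed,
             provenance = list(defocus = sim$aberrations$defocus,
                               transmitted_fraction = f_el + f_inel,
                               phantom_px = n, phantom_pixel_size = p))
}

#' Attenuation curves for filtered and unfiltered collection
#'
#' Retained signal fraction versus thickness for the energy-filtered channel
#' (decay constant: high-angle-corrected inelastic mean free path) and the
#' unfiltered bright-field channel (elastic mean free path). Their ratio is
#' exp(t / lambda_eff).
#'
#' @param thickness_grid Thicknesses (nm).
#' @param model An [mfp_model()] with `lambda_el` set.
#' @return List with `thickness`, `eftem_fraction`, `tcbf_fraction`.
#' @export
attenuation_pair <- function(thickness_grid, model) {
  if (is.null(model$lambda_el)) {
    stop("model must include lambda_el", call. = FALSE)
  }
  list(thickness = thickness_grid,
       eftem_fraction = exp(-thickness_grid / model$lambda_in_prime),
       tcbf_fraction = exp(-thickness_grid / model$lambda_el))
}
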