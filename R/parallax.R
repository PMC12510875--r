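#' Locate the bright-field disk on the detector
#'
#' Thresholds the scan-averaged diffraction pattern at a fraction of its
#' robust maximum, then fits the disk centre by intensity-weighted centroid
#' and the radius as the equivalent-area radius. Detector pixels within
#' `edge_margin` pixels of the fitted rim are down-weighted (the transfer
#' function differs toward the aperture edge and rim pixels can register
#' falsely).
#'
#' @param cube A [datacube4d()].
#' @param threshold Fraction of the robust (99th percentile) maximum.
#' @param edge_margin Rim exclusion width (detector pixels).
#' @param edge_weight Weight applied to rim pixels (0 removes them).
#' @return Object of class `bf_mask`: logical `mask`, `center` (0-based
#'   fractional c(row, col)), `radius_px`, `radius_rad`, `weights` matrix.
#' @export
find_bf_disk <- function(cube, threshold = 0.5, edge_margin = 1,
                         edge_weight = 0.5) {
  mean_cbed <- apply(cube$counts, c(3, 4), mean)
  top <- stats::quantile(mean_cbed, 0.99, names = FALSE)
  if (!is.finite(top) || top <= 0) {
    stop("no bright-field disk detected: mean pattern is empty",
         call. = FALSE)
  }
  hard <- mean_cbed >= threshold * top
  if (!any(hard)) stop("no bright-field disk detected", call. = FALSE)
  w <- mean_cbed * hard
  rows <- row(mean_cbed) - 1; cols <- col(mean_cbed) - 1
  ctr <- c(sum(rows * w), sum(cols * w)) / sum(w)
  radius <- sqrt(sum(hard) / pi)
  dist <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  mask <- dist <= radius
  weights <- matrix(0, nrow(mask), ncol(mask))
  weights[mask] <- 1
  rim <- mask & dist > (radius - edge_margin)
  weights[rim] <- edge_weight
  structure(list(mask = mask, center = ctr, radius_px = radius,
                 radius_rad = radius * cube$det_pixel, weights = weights),
            class = "bf_mask")
}

#' @export
print.bf_mask <- function(x, ...) {
  cat(sprintf("<bf_mask> %d px, centre (%.2f, %.2f), radius %.2f px = %.3f mrad\n",
              sum(x$mask), x$center[1], x$center[2], x$radius_px,
              1e3 * x$radius_rad))
  invisible(x)
}

#' Bright-field mask for shift measurement
#'
#' Like [find_bf_disk()], but excludes the outer annulus of the disk whose
#' width equals the half-width of the scan passband, lambda / (2 * scan
#' step), expressed as a detector angle. For detector pixels inside this
#' margin every image frequency the scan can sample lies in the
#' triple-overlap region, so the virtual image is an exactly shifted copy
#' of the axial image and registration is unbiased; rim pixels carry
#' single-sideband contamination that biases measured shifts.
#'
#' @param cube A [datacube4d()] with optics metadata.
#' @param scan_step Scan step (A); defaults to the cube's.
#' @return A `bf_mask` with the rim annulus given zero weight.
#' @export
shift_measurement_mask <- function(cube, scan_step = cube$scan_step) {
  margin_px <- 1
  if (!is.null(cube$optics)) {
    band_angle <- cube$optics$lambda / (2 * scan_step)
    # + 0.5: a detector pixel has finite width, so its whole area must
    # stay clear of the single-sideband annulus
    margin_px <- max(1, band_angle / cube$det_pixel + 0.5)
  }
  find_bf_disk(cube, edge_margin = margin_px, edge_weight = 0)
}

#' Virtual image from selected detector pixels
#'
#' Scan-shaped image of the counts collected by one detector pixel or the
#' sum over a set of pixels.
#'
#' @param cube A [datacube4d()].
#' @param pixels Integer 2-vector c(row, col) or an n x 2 matrix of
#'   detector pixel indices (1-based).
#' @return Matrix of scan shape.
#' @export
virtual_image <- function(cube, pixels) {
  px <- if (is.matrix(pixels)) pixels else matrix(pixels, ncol = 2)
  d <- dim(cube$counts)
  if (any(px < 1) || any(px[, 1] > d[3]) || any(px[, 2] > d[4])) {
    stop("detector pixel index out of range", call. = FALSE)
  }
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(px))) {
    out <- out + cube$counts[, , px[i, 1], px[i, 2]]
  }
  out
}

# Cross-correlation shift of img relative to ref: returns w = c(dy, dx) such
# that img(x) ~ ref(x - w), with sub-pixel refinement by a local upsampled
# DFT of the cross-power spectrum. filter: "phase" whitens fully, "hybrid"
# whitens by sqrt, "cross" leaves amplitudes.
xcorr_shift <- function(ref, img, upsample = 16,
                        filter = c("phase", "hybrid", "cross"),
                        lowpass = NULL) {
  filter <- match.arg(filter)
  n1 <- nrow(ref); n2 <- ncol(ref)
  F1 <- fft2(ref - mean(ref)); F2 <- fft2(img - mean(img))
  R <- F2 * Conj(F1)
  if (!is.null(lowpass) && lowpass > 0) {
    fy <- fft_freq(n1); fx <- fft_freq(n2)
    R <- R * exp(-2 * pi^2 * lowpass^2 *
                   (outer(fy^2, rep(1, n2)) + outer(rep(1, n1), fx^2)))
  }
  Rw <- switch(filter,
               phase  = R / pmax(Mod(R), 1e-12),
               hybrid = R / pmax(sqrt(Mod(R)), 1e-12),
               cross  = R)
  cc <- Re(ifft2(Rw))
  pk <- arrayInd(which.max(cc), dim(cc))
  # integer shift with wrap into [-n/2, n/2)
  wy <- pk[1] - 1L; wx <- pk[2] - 1L
  if (wy > n1 / 2) wy <- wy - n1
  if (wx > n2 / 2) wx <- wx - n2
  # local upsampled DFT refinement around the integer peak
  u <- max(1L, as.integer(upsample))
  if (u > 1) {
    span <- 1.5
    ys <- wy + seq(-span, span, by = 1 / u)
    xs <- wx + seq(-span, span, by = 1 / u)
    ky <- fft_freq(n1) ; kx <- fft_freq(n2)     # cycles/px
    Ey <- exp(2i * pi * outer(ys, ky))          # |ys| x n1
    Ex <- exp(2i * pi * outer(kx, xs))          # n2 x |xs|
    local <- Re(Ey %*% Rw %*% Ex)
    pk2 <- arrayInd(which.max(local), dim(local))
    wy <- ys[pk2[1]]; wx <- xs[pk2[2]]
  }
  # registration confidence: normalized correlation coefficient at the peak
  ccn <- Re(ifft2(R))
  denom <- sqrt(sum((ref - mean(ref))^2) * sum((img - mean(img))^2))
  conf <- if (denom > 0) max(ccn) / denom else 0
  list(shift = c(wy, wx), weight = max(0, min(1, conf)))
}

#' Measure the parallax shift field
#'
#' Registers every masked detector pixel's virtual image against the
#' axial-pixel image by cross-correlation with sub-pixel (upsampled-DFT)
#' refinement; subsequent iterations re-register against the running
#' shift-corrected mean. The shift W(Theta) is the translation mapping the
#' reference onto the pixel image; for pure defocus W = df * Theta,
#' pointing outward for positive defocus. The axial-pixel shift is pinned
#' to zero.
#'
#' @param cube A [datacube4d()].
#' @param mask A [find_bf_disk()] result (computed if NULL).
#' @param xcorr_upsample Sub-pixel refinement factor.
#' @param max_iter Alignment iterations (1 = axial reference only).
#' @param tol Convergence tolerance for the max shift update (scan pixels).
#' @param filter Correlation whitening: "phase", "hybrid" or "cross".
#' @param lowpass Optional Gaussian low-pass sigma (scan pixels) applied in
#'   the correlation.
#' @param det_smooth Detector-neighborhood radius used only for the
#'   registration images: each pixel is registered from the average of its
#'   (2r+1)^2 neighbours. The parallax shift varies by just df * dalpha
#'   between neighbours, so this trades negligible shift blur for an
#'   r-fold gain in counting statistics at low dose. 0 disables.
#' @return Object of class `shift_field`: a data frame with one row per
#'   masked detector pixel (`det_row`, `det_col`, `theta_x`, `theta_y` in
#'   rad, `wx_A`, `wy_A` in Angstrom, `weight`), with the cube calibration
#'   and iteration diagnostics in attributes.
#' @export
measure_shifts <- function(cube, mask = NULL, xcorr_upsample = 16,
                           max_iter = 3, tol = 0.05,
                           filter = "phase", lowpass = NULL,
                           det_smooth = 1) {
  if (is.null(mask)) mask <- find_bf_disk(cube)
  sel <- which(mask$mask & mask$weights > 0, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("mask is empty", call. = FALSE)
  th <- detector_angles(cube)
  npx <- nrow(sel)
  reg_counts <- cube$counts
  if (det_smooth > 0) {
    # average each pixel's image with its detector neighbours (inside the
    # disk) before registration; purely a measurement-side SNR boost
    d <- dim(cube$counts)
    acc <- array(0, d); nrm <- array(0, d[3:4])
    inside <- mask$mask
    r <- as.integer(det_smooth)
    for (dy in -r:r) for (dx in -r:r) {
      ry <- seq_len(d[3]) + dy; rx <- seq_len(d[4]) + dx
      oky <- ry >= 1 & ry <= d[3]; okx <- rx >= 1 & rx <= d[4]
      src_in <- inside[ry[oky], rx[okx]]
      acc[, , oky, okx] <- acc[, , oky, okx] +
        sweep(cube$counts[, , ry[oky], rx[okx], drop = FALSE],
              c(3, 4), src_in, `*`)
      nrm[oky, okx] <- nrm[oky, okx] + src_in
    }
    reg_counts <- sweep(acc, c(3, 4), pmax(nrm, 1), `/`)
  }
  imgs <- vector("list", npx)
  for (i in seq_len(npx)) {
    imgs[[i]] <- reg_counts[, , sel[i, 1], sel[i, 2]]
  }
  sds <- vapply(imgs, stats::sd, numeric(1))
  scale_ref <- mean(vapply(imgs, function(x) mean(abs(x)), numeric(1)))
  if (all(sds <= 1e-10 * (scale_ref + .Machine$double.eps))) {
    stop("degenerate registration: all virtual images are flat",
         call. = FALSE)
  }
  # axial pixel = masked pixel nearest the fitted centre
  d_ctr <- sqrt((sel[, 1] - 1 - mask$center[1])^2 +
                (sel[, 2] - 1 - mask$center[2])^2)
  axial <- which.min(d_ctr)
  ref <- imgs[[axial]]
  W <- matrix(0, npx, 2)                 # (wy, wx) in scan pixels
  wt <- numeric(npx)
  iter_done <- 0L; converged <- FALSE
  for (it in seq_len(max(1L, max_iter))) {
    W_old <- W
    for (i in seq_len(npx)) {
      r <- xcorr_shift(ref, imgs[[i]], upsample = xcorr_upsample,
                       filter = filter, lowpass = lowpass)
      W[i, ] <- r$shift
      wt[i] <- r$weight
    }
    W <- sweep(W, 2, W[axial, ])         # pin the axial pixel to zero
    iter_done <- it
    upd <- max(sqrt(rowSums((W - W_old)^2)))
    if (it > 1 && upd < tol) { converged <- TRUE; break }
    if (it < max_iter) {
      # running shift-corrected mean as the next reference
      acc <- matrix(0, nrow(ref), ncol(ref)); tw <- 0
      ew <- mask$weights[cbind(sel[, 1], sel[, 2])] * wt
      for (i in seq_len(npx)) {
        acc <- acc + ew[i] * fourier_shift(imgs[[i]], -W[i, 1], -W[i, 2])
        tw <- tw + ew[i]
      }
      ref <- acc / tw
    }
  }
  if (max_iter > 1 && !converged && iter_done == max_iter) {
    # last iterate returned; informative, not fatal
    message("measure_shifts: not converged after ", max_iter, " iterations")
  }
  sf <- data.frame(
    det_row = sel[, 1], det_col = sel[, 2],
    theta_x = th$theta_x[sel], theta_y = th$theta_y[sel],
    wx_A = W[, 2] * cube$scan_step, wy_A = W[, 1] * cube$scan_step,
    weight = wt * mask$weights[cbind(sel[, 1], sel[, 2])])
  structure(sf, class = c("shift_field", "data.frame"),
            scan_step = cube$scan_step, det_pixel = cube$det_pixel,
            axial_index = axial, iterations = iter_done,
            converged = converged)
}

#' Fit an aberration surface to a measured shift field
#'
#' Weighted least squares of W(Theta) against the gradient model
#' W = -(1/k0) grad chi(Theta): defocus gives W = df * Theta, twofold
#' astigmatism adds (a Tx + b Ty, b Tx - a Ty) with a = A1 cos 2phi_A,
#' b = A1 sin 2phi_A, and third-order spherical aberration adds
#' C3 |Theta|^2 Theta.
#'
#' @param shifts A [measure_shifts()] result.
#' @param cfg An [optical_config()] (wavelength bookkeeping; the linear
#'   model itself is wavelength-free).
#' @param order Terms to fit: "defocus", "astigmatism" (with defocus), or
#'   "spherical" (defocus + astigmatism + C3).
#' @return Object of class `aberration_fit`: `surface` (an
#'   [aberration_surface()]), `residuals` (n x 2, A), `rms` (A),
#'   `coefficients`.
#' @export
fit_aberration_surface <- function(shifts, cfg,
                                   order = c("astigmatism", "defocus",
                                             "spherical")) {
  order <- match.arg(order)
  tx <- shifts$theta_x; ty <- shifts$theta_y
  w <- shifts$weight
  n <- length(tx)
  cols <- list(defocus = c(tx, ty))
  if (order %in% c("astigmatism", "spherical")) {
    cols$astig_a <- c(tx, -ty)
    cols$astig_b <- c(ty, tx)
  }
  if (order == "spherical") {
    t2 <- tx^2 + ty^2
    cols$c3 <- c(t2 * tx, t2 * ty)
  }
  X <- do.call(cbind, cols)
  if (2 * n < ncol(X)) {
    stop("fitting error: fewer weighted shifts than parameters",
         call. = FALSE)
  }
  y <- c(shifts$wx_A, shifts$wy_A)
  ww <- rep(pmax(w, 0), 2)
  fit <- stats::lm.wfit(X, y, ww)
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop("fitting error: unresolvable parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- fit$coefficients
  a <- if ("astig_a" %in% names(cf)) cf[["astig_a"]] else 0
  b <- if ("astig_b" %in% names(cf)) cf[["astig_b"]] else 0
  surf <- aberration_surface(
    defocus = cf[["defocus"]],
    astig_mag = sqrt(a^2 + b^2),
    astig_angle = if (a != 0 || b != 0) atan2(b, a) / 2 else 0,
    c3 = if ("c3" %in% names(cf)) cf[["c3"]] else 0)
  res <- matrix(fit$residuals, ncol = 2)
  rms <- sqrt(sum(ww * fit$residuals^2) / sum(ww))
  structure(list(surface = surf, residuals = res, rms = rms,
                 coefficients = cf, cfg = cfg),
            class = "aberration_fit")
}

#' @export
print.aberration_fit <- function(x, ...) {
  cat(sprintf("<aberration_fit> defocus %.1f A", x$surface$defocus))
  if (x$surface$astig_mag > 0) {
    cat(sprintf(", A1 %.1f A @ %.1f deg", x$surface$astig_mag,
                x$surface$astig_angle * 180 / pi))
  }
  cat(sprintf("; residual RMS %.3f A\n", x$rms))
  invisible(x)
}

# Model-predicted shifts (A) at the shift field's detector angles.
predict_shifts <- function(surface, shifts) {
  tx <- shifts$theta_x; ty <- shifts$theta_y
  a <- surface$astig_mag * cos(2 * surface$astig_angle)
  b <- surface$astig_mag * sin(2 * surface$astig_angle)
  t2 <- tx^2 + ty^2
  cbind(wx = surface$defocus * tx + a * tx + b * ty + surface$c3 * t2 * tx,
        wy = surface$defocus * ty + b * tx - a * ty + surface$c3 * t2 * ty)
}

#' Regularize a shift field with a fitted aberration surface
#'
#' `replace` substitutes the model-predicted shifts everywhere; `blend`
#' combines measurement and model per pixel using the registration
#' confidence as the measurement weight. The axial pixel stays at zero.
#'
#' @param shifts A [measure_shifts()] result.
#' @param fitted An [aberration_fit()] or [aberration_surface()].
#' @param mode "replace" or "blend".
#' @return A `shift_field` with updated `wx_A`, `wy_A`.
#' @export
regularize_shifts <- function(shifts, fitted, mode = c("replace", "blend")) {
  mode <- match.arg(mode)
  surf <- if (inherits(fitted, "aberration_fit")) fitted$surface else fitted
  pred <- predict_shifts(surf, shifts)
  axial <- attr(shifts, "axial_index")
  pred <- sweep(pred, 2, pred[axial, ])  # model is zero at the axial pixel
  out <- shifts
  if (mode == "replace") {
    out$wx_A <- pred[, "wx"]; out$wy_A <- pred[, "wy"]
  } else {
    cw <- pmin(pmax(shifts$weight / max(shifts$weight), 0), 1)
    out$wx_A <- cw * shifts$wx_A + (1 - cw) * pred[, "wx"]
    out$wy_A <- cw * shifts$wy_A + (1 - cw) * pred[, "wy"]
  }
  out
}

#' Shift-corrected, upsampled tcBF reconstruction
#'
#' Places every masked detector pixel's virtual-image samples onto a grid
#' refined by the integer factor `s`, at positions corrected by minus the
#' pixel's measured shift, with bilinear kernel splatting; the accumulated
#' image is divided by the accumulated coverage (the kernel-density
#' estimate over the sub-pixel shift distribution). Also returns the
#' uncorrected sum (all shifts zero) for before/after comparison; for
#' s > 1 the uncorrected sum is zero-pad Fourier-upsampled onto the same
#' grid.
#'
#' @param cube A [datacube4d()].
#' @param shifts A [measure_shifts()] (or regularized) shift field.
#' @param upsample_factor Integer s >= 1; values above the recommended
#'   bound alpha/delta_alpha warn.
#' @param padding Interpolation used for the uncorrected comparison image
#'   ("zero" = zero-padded Fourier upsampling).
#' @param weighting Accumulation scheme; "subpixel_kde" kernel-density
#'   gridding.
#' @param kernel_sigma Gaussian gridding-kernel width (fine pixels); its
#'   response is deconvolved from the final image.
#' @return Object of class `tcbf_reconstruction`: `image`, `coverage`,
#'   `uncorrected`, `upsample`, `pixel_size` (A).
#' @export
reconstruct_tcbf <- function(cube, shifts, upsample_factor = 1,
                             padding = "zero", weighting = "subpixel_kde",
                             kernel_sigma = 0.6) {
  s <- upsample_factor
  if (length(s) != 1 || !is.finite(s) || s < 1 || s != round(s)) {
    stop("upsample_factor must be a positive integer", call. = FALSE)
  }
  s <- as.integer(s)
  if (!is.null(cube$optics) && !is.null(cube$optics$alpha)) {
    bound <- cube$optics$alpha / cube$det_pixel
    if (s > bound) {
      warning(sprintf(
        "upsample factor %d exceeds the recommended bound alpha/dalpha = %.1f",
        s, bound))
    }
  }
  d <- dim(cube$counts)
  ny <- d[1]; nx <- d[2]
  NY <- ny * s; NX <- nx * s
  fine_px <- cube$scan_step / s
  num <- matrix(0, NY, NX); cov <- matrix(0, NY, NX)
  base_y <- rep(seq_len(ny) - 1L, times = nx) * s
  base_x <- rep(seq_len(nx) - 1L, each = ny) * s
  plain <- matrix(0, ny, nx)
  if (s == 1) {
    # exact sub-pixel correction by Fourier phase ramps; no kernel footprint
    tw <- 0
    for (k in seq_len(nrow(shifts))) {
      w <- shifts$weight[k]
      if (w <= 0) next
      img <- cube$counts[, , shifts$det_row[k], shifts$det_col[k]]
      plain <- plain + w * img
      num <- num + w * fourier_shift(img, -shifts$wy_A[k] / fine_px,
                                     -shifts$wx_A[k] / fine_px)
      tw <- tw + w
    }
    cov[] <- tw
    image <- num / tw
    ok <- cov > 0
  } else {
    # Gaussian kernel-density gridding on the s-fine grid, followed by
    # exact Fourier deconvolution of the kernel response
    sig <- kernel_sigma
    rad <- max(2L, as.integer(ceiling(3 * sig)))
    offs <- expand.grid(dy = -rad:rad, dx = -rad:rad)
    for (k in seq_len(nrow(shifts))) {
      w <- shifts$weight[k]
      if (w <= 0) next
      img <- cube$counts[, , shifts$det_row[k], shifts$det_col[k]]
      plain <- plain + w * img
      py <- base_y - shifts$wy_A[k] / fine_px   # apply -W
      px <- base_x - shifts$wx_A[k] / fine_px
      y0 <- round(py); x0 <- round(px)
      ry <- py - y0; rx <- px - x0
      v <- as.vector(img) * w
      for (o in seq_len(nrow(offs))) {
        dy <- offs$dy[o]; dx <- offs$dx[o]
        bw <- exp(-((dy - ry)^2 + (dx - rx)^2) / (2 * sig^2))
        iy <- ((y0 + dy) %% NY) + 1L; ix <- ((x0 + dx) %% NX) + 1L
        idx <- iy + (ix - 1L) * NY
        num[idx] <- num[idx] + v * bw
        cov[idx] <- cov[idx] + w * bw
      }
    }
    floor_cov <- 1e-12 * max(cov)
    image <- num / pmax(cov, floor_cov)
    ok <- cov > floor_cov
    # kernel deconvolution (bounded gain; the kernel is well above the
    # floor for all frequencies of interest)
    fy <- fft_freq(NY); fx <- fft_freq(NX)
    G <- exp(-2 * pi^2 * sig^2 * (outer(fy^2, rep(1, NX)) +
                                  outer(rep(1, NY), fx^2)))
    image <- Re(ifft2(fft2(image) / pmax(G, 0.05)))
  }
  tw <- sum(shifts$weight[shifts$weight > 0])
  uncorrected <- if (s == 1) plain else fourier_upsample(plain, s)
  structure(list(image = image, coverage = cov,
                 uncorrected = uncorrected / max(tw, .Machine$double.eps),
                 upsample = s, pixel_size = fine_px,
                 n_pixels = sum(shifts$weight > 0)),
            class = "tcbf_reconstruction")
}

#' @export
print.tcbf_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<tcbf_reconstruction> %d x %d @ %.3f A (upsample %d), %d detector px\n",
    nrow(x$image), ncol(x$image), x$pixel_size, x$upsample, x$n_pixels))
  invisible(x)
}

#' Radial power spectrum of an image
#'
#' Azimuthal mean of |FFT|^2 versus spatial frequency.
#'
#' @param image 2-D matrix.
#' @param pixel_size Pixel size (A).
#' @return Data frame with `q` (1/A, annulus centres) and `power`.
#' @export
radial_power_spectrum <- function(image, pixel_size) {
  stopifnot(is.matrix(image))
  # normalized so amplitudes are comparable across sampling rates
  P <- Mod(fft2(image - mean(image)) / length(image))^2
  n1 <- nrow(image); n2 <- ncol(image)
  fy <- fft_freq(n1, pixel_size); fx <- fft_freq(n2, pixel_size)
  q <- sqrt(outer(fy^2, rep(1, n2)) + outer(rep(1, n1), fx^2))
  dq <- 1 / (max(n1, n2) * pixel_size)
  bin <- pmax(1L, as.integer(round(q / dq)))
  agg <- tapply(as.vector(P), as.vector(bin), mean)
  data.frame(q = as.numeric(names(agg)) * dq, power = as.numeric(agg))
}

#' DPC and iDPC images from a datacube
#'
#' Differential phase-contrast images along both scan axes from the
#' bright-field disk, and the integrated-DPC image obtained by Fourier
#' integration (division by i(kx + i ky), DC bin zeroed). Detector pixels
#' are combined with tilt-proportional (centre-of-mass) weights by
#' default, or with half-plane sign weights.
#'
#' @param cube A [datacube4d()].
#' @param mask A [find_bf_disk()] result (computed if NULL).
#' @param weighting "com" (tilt-weighted) or "sign" (half-plane difference).
#' @return List with `dpc_x`, `dpc_y`, `idpc` matrices of scan shape.
#' @export
dpc_images <- function(cube, mask = NULL, weighting = c("com", "sign")) {
  weighting <- match.arg(weighting)
  if (is.null(mask)) mask <- find_bf_disk(cube)
  th <- detector_angles(cube)
  wx <- th$theta_x; wy <- th$theta_y
  if (weighting == "com") {
    wx <- wx / cube$optics$alpha; wy <- wy / cube$optics$alpha
  } else {
    wx <- sign(wx); wy <- sign(wy)
  }
  wx[!mask$mask] <- 0; wy[!mask$mask] <- 0
  d <- dim(cube$counts)
  dpc_x <- matrix(0, d[1], d[2]); dpc_y <- matrix(0, d[1], d[2])
  sel <- which(mask$mask, arr.ind = TRUE)
  for (i in seq_len(nrow(sel))) {
    img <- cube$counts[, , sel[i, 1], sel[i, 2]]
    dpc_x <- dpc_x + wx[sel[i, 1], sel[i, 2]] * img
    dpc_y <- dpc_y + wy[sel[i, 1], sel[i, 2]] * img
  }
  # Fourier integration: iDPC = (DPCx + i DPCy) / (i (kx + i ky)), DC = 0
  n1 <- d[1]; n2 <- d[2]
  ky <- fft_freq(n1, cube$scan_step); kx <- fft_freq(n2, cube$scan_step)
  KX <- outer(rep(1, n1), kx); KY <- outer(ky, rep(1, n2))
  denom <- 1i * (KX + 1i * KY)
  Fi <- (fft2(dpc_x) + 1i * fft2(dpc_y)) / denom
  Fi[1, 1] <- 0
  idpc <- Re(ifft2(Fi))
  list(dpc_x = dpc_x, dpc_y = dpc_y, idpc = idpc)
}
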