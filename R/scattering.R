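#' Inelastic mean free path presets at 300 kV
#'
#' Literature inelastic mean free paths (nm) used for thickness estimation:
#' vitreous ice 310 nm, protein 275 nm, amorphous carbon 100 nm.
#' @export
MFP_PRESETS <- c(ice = 310, protein = 275, carbon = 100)

#' High-angle-corrected inelastic mean free path
#'
#' An energy-filtered image loses intensity both to inelastic scattering and
#' to high-angle elastic scattering that misses the detector. With
#' lambda_HA = a_HA * lambda_in, the combined decay constant is
#' \deqn{\lambda_{in}' = \frac{a_{HA}}{a_{HA}+1}\lambda_{in}}
#'
#' @param lambda_in Inelastic mean free path (nm, > 0).
#' @param a_HA Dimensionless ratio lambda_HA / lambda_in (> 0); 46 measured
#'   for the instrument conditions this package models.
#' @return Corrected mean free path (nm).
#' @examples
#' lambda_in_prime(310, 46)  # 303.4 nm, 0.979 * lambda_in
#' @export
lambda_in_prime <- function(lambda_in, a_HA) {
  if (any(lambda_in <= 0) || any(a_HA <= 0)) {
    stop("lambda_in and a_HA must be > 0", call. = FALSE)
  }
  lambda_in * a_HA / (a_HA + 1)
}

#' Effective mean free path for the tcBF/EFTEM dose advantage
#'
#' The ratio of the unfiltered (elastic-decay) to filtered
#' (inelastic-decay) signal grows as exp(t / lambda_eff) with
#' 1/lambda_eff = 1/lambda_in - 1/lambda_el, defined for
#' lambda_el > lambda_in.
#'
#' @param lambda_el Elastic mean free path (nm).
#' @param lambda_in Inelastic mean free path (nm).
#' @return Effective mean free path (nm).
#' @examples
#' lambda_eff(830, 310)  # ~495 nm
#' @export
lambda_eff <- function(lambda_el, lambda_in) {
  if (any(lambda_in <= 0)) stop("lambda_in must be > 0", call. = FALSE)
  if (any(lambda_el <= lambda_in)) {
    stop("invalid model: lambda_el must exceed lambda_in for a positive ",
         "effective mean free path", call. = FALSE)
  }
  1 / (1 / lambda_in - 1 / lambda_el)
}

#' Dose advantage of unfiltered over energy-filtered imaging
#'
#' exp(t / lambda_eff): the signal-retention ratio of an unfiltered
#' bright-field image to an energy-filtered image at thickness t.
#'
#' @param thickness Thickness (nm).
#' @param lambda_eff_nm Effective mean free path (nm, > 0).
#' @return Dimensionless ratio (>= 1 for t >= 0).
#' @examples
#' dose_advantage(400, lambda_eff(830, 310))  # ~2.2
#' @export
dose_advantage <- function(thickness, lambda_eff_nm) {
  if (any(lambda_eff_nm <= 0)) stop("lambda_eff must be > 0", call. = FALSE)
  exp(thickness / lambda_eff_nm)
}

#' Mean-free-path model
#'
#' State for thickness and dose-efficiency calculations: the inelastic mean
#' free path, the high-angle ratio, the derived corrected inelastic path,
#' and (optionally) the elastic path with the derived effective path.
#'
#' @param lambda_in Inelastic mean free path (nm); default vitreous ice.
#' @param a_HA High-angle ratio lambda_HA/lambda_in; default 46.
#' @param lambda_el Elastic mean free path (nm), optional.
#' @param I0 Reference incident intensity (electrons), default 1.
#' @return An object of class `mfp_model`.
#' @export
mfp_model <- function(lambda_in = MFP_PRESETS[["ice"]], a_HA = 46,
                      lambda_el = NULL, I0 = 1) {
  m <- list(lambda_in = lambda_in, a_HA = a_HA,
            lambda_in_prime = lambda_in_prime(lambda_in, a_HA),
            lambda_el = lambda_el, I0 = I0)
  m$lambda_eff <- if (!is.null(lambda_el)) lambda_eff(lambda_el, lambda_in)
  structure(m, class = "mfp_model")
}

#' @export
print.mfp_model <- function(x, ...) {
  cat(sprintf("<mfp_model> lambda_in = %g nm (a_HA = %g -> %.1f nm corrected)",
              x$lambda_in, x$a_HA, x$lambda_in_prime))
  if (!is.null(x$lambda_el)) {
    cat(sprintf("  lambda_el = %g nm  lambda_eff = %.1f nm",
                x$lambda_el, x$lambda_eff))
  }
  cat("\n")
  invisible(x)
}

#' Thickness from the retained electron fraction
#'
#' Inverts the exponential attenuation of a filtered image,
#' t = -lambda * ln(fraction), with lambda the inelastic mean free path
#' (default) or its high-angle-corrected value when `corrected = TRUE`.
#' Fractions <= 0 yield NA (masked); fractions > 1 are invalid.
#'
#' @param fraction Retained fraction(s) of incident electrons, in (0, 1].
#' @param model An [mfp_model()].
#' @param corrected Use the high-angle-corrected mean free path.
#' @return Thickness (nm), NA where the fraction is non-positive.
#' @examples
#' thickness_from_fraction(0.171, mfp_model(310))  # 547.5 nm
#' @export
thickness_from_fraction <- function(fraction, model = mfp_model(),
                                    corrected = FALSE) {
  if (any(fraction > 1, na.rm = TRUE)) {
    stop("fraction must be <= 1", call. = FALSE)
  }
  lam <- if (corrected) model$lambda_in_prime else model$lambda_in
  out <- rep(NA_real_, length(fraction))
  ok <- !is.na(fraction) & fraction > 0
  out[ok] <- -lam * log(fraction[ok])
  out
}

#' Elastic mean free path from unfiltered fractions vs thickness
#'
#' Through-origin least squares of ln(fraction) against -t: the unfiltered
#' signal decays as exp(-t/lambda_el), and the fraction at t = 0 is 1 by
#' construction, so the intercept is fixed at zero. Returns the fitted
#' lambda_el with the standard error of the decay slope propagated to it.
#'
#' @param thicknesses Thicknesses (nm).
#' @param fractions Retained unfiltered fractions in (0, 1].
#' @return List with `lambda_el` (nm), `se` (nm), `slope` (1/nm), `n`.
#' @examples
#' fit_elastic_mfp(c(547, 673, 596), c(0.533, 0.403, 0.522))
#' @export
fit_elastic_mfp <- function(thicknesses, fractions) {
  ok <- is.finite(thicknesses) & is.finite(fractions) &
    fractions > 0 & fractions <= 1
  t <- thicknesses[ok]; y <- log(fractions[ok])
  if (length(t) < 2) {
    stop("insufficient data: need >= 2 valid (thickness, fraction) points",
         call. = FALSE)
  }
  # y = -t / lambda; through-origin slope b = sum(x y)/sum(x^2) with x = -t
  b <- -sum(t * y) / sum(t^2)          # b = 1/lambda_el
  res <- y + b * t
  dfree <- length(t) - 1L
  se_b <- if (dfree > 0) sqrt(sum(res^2) / dfree / sum(t^2)) else 0
  list(lambda_el = 1 / b, se = se_b / b^2, slope = -b, n = length(t))
}

#' Per-pixel thickness map from a filtered image
#'
#' Divides the energy-filtered image by the incident intensity (a scalar
#' dose or a co-registered unfiltered reference image) and inverts the
#' attenuation model per pixel. Pixels whose fraction falls outside (0, 1]
#' are masked (NA).
#'
#' @param filtered Energy-filtered image (matrix).
#' @param incident Scalar incident intensity, or a matrix of the same shape.
#' @param model An [mfp_model()].
#' @param corrected Use the high-angle-corrected mean free path.
#' @return An object of class `thickness_map`: list with `values` (matrix,
#'   nm), `mask` (logical matrix of valid pixels), `model`, `source`.
#' @export
thickness_map <- function(filtered, incident, model = mfp_model(),
                          corrected = FALSE) {
  stopifnot(is.matrix(filtered))
  if (is.matrix(incident)) {
    if (!all(dim(incident) == dim(filtered))) {
      stop("filtered and incident images must have the same shape",
           call. = FALSE)
    }
    frac <- filtered / incident
  } else {
    frac <- filtered / incident[[1]]
  }
  valid <- is.finite(frac) & frac > 0 & frac <= 1
  vals <- matrix(NA_real_, nrow(frac), ncol(frac))
  lam <- if (corrected) model$lambda_in_prime else model$lambda_in
  vals[valid] <- -lam * log(frac[valid])
  structure(list(values = vals, mask = valid, model = model,
                 source = "eftem_fraction"),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<thickness_map> %d x %d, %d valid px, mean %.1f nm\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              if (length(v)) mean(v) else NA_real_))
  invisible(x)
}
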