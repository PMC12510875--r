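---
title: "Tilt-corrected bright-field STEM: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tilt-corrected bright-field STEM: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcbfstem)
```

# The imaging problem

Thick biological specimens scatter most electrons inelastically. After one
inelastic mean free path (λ_in ≈ 310 nm in vitreous ice at 300 kV) only
1/e of the beam remains unscattered in energy; an energy filter, the
standard remedy for the chromatic blur those electrons would otherwise
cause, throws the rest away. Scanning the specimen with a defocused
convergent probe and recording the full diffraction pattern at every
position keeps them: each detector pixel inside the bright-field (BF) disk
forms, by reciprocity, a tilted-illumination bright-field image, and
because inelastic scattering only slightly blurs the angular distribution
(most-probable inelastic angles are far smaller than the aperture), those
images remain usable without filtering. The catch is that under the
defocus Δf needed for phase contrast, the image formed at detector angle
Θ is displaced by the parallax shift

$$W(\Theta) = \Delta f\,\Theta,$$

so a naive sum is blurred over the geometric disk 2αΔf. Tilt-corrected
bright-field STEM (tcBF-STEM) measures the per-pixel shifts, undoes them,
and sums.

# Contrast transfer

## Tilted-beam PCTF

For a weak-phase object, the image formed at detector angle Θ has the
phase-contrast transfer function

$$\mathrm{PCTF}(\omega,\Theta)=\tfrac{i}{2}A(\Theta)\left\{
A(\omega-\Theta)e^{-i[\chi(\omega-\Theta)-\chi(\Theta)]}-
A(\omega+\Theta)e^{+i[\chi(\omega+\Theta)-\chi(\Theta)]}\right\},$$

with $A$ the aperture indicator (cutoff α), ω the image spatial frequency
expressed as a scattering angle, and χ the aberration phase; for pure
defocus $\chi(\Theta)=-\tfrac12 k_0\,\Delta f\,|\Theta|^2$ with
$k_0=2\pi/\lambda$. We absorb the solid-angle prefactor of the continuum
form into the ½ so that $|\mathrm{PCTF}|\le 1$; overall sign is a display
convention (tests compare magnitudes and zero crossings). At Θ = 0 this
reduces to the axial BF CTF $\sin\chi(\omega)$ with support to α; at
|Θ| = α the support extends to 2α. Where both diffracted disks ±ω overlap
the unscattered beam (the *triple-overlap* region) the two exponentials
interfere and the amplitude can reach twice the *double-overlap*
(single-sideband) value — `overlap_region()` classifies a detector point,
and `pctf_tilted()` reproduces the 2:1 amplitude ratio.

## The tcBF CTF

Summing the tilt-corrected single-pixel PCTFs over the disk collapses, for
defocus-only aberrations, to a closed form,

$$\mathrm{CTF}_{\mathrm{tcBF}}(\omega)=
-\mathcal L(\omega/\alpha)\,\sin\!\left(\tfrac12 k_0 \Delta f\,\omega^2\right),
\qquad
\mathcal L(u)=\tfrac{2}{\pi}\left[\cos^{-1}\tfrac u2-\tfrac u2
\sqrt{1-\tfrac{u^2}{4}}\right],$$

where $\mathcal L$ is the familiar self-luminous (ADF) disk-overlap
envelope: unit at zero, zero at $u=2$. Two properties matter in practice
and are asserted by the tests: the zero crossings inside (0, α] coincide
exactly with the axial BF CTF (so conventional CTF-estimation tools apply
to tcBF images), and information transfer extends to 2α — twice the axial
limit. `ctf_tcbf_numeric()` integrates the paired tilt sum over the half
disk on a Cartesian grid with fractional-area (antialiased) rim weights;
at the default 256 samples across the diameter it agrees with the closed
form to better than 10⁻³, and the quadrature, not the closed form, is what
the equivalence test trusts as the independent route.

## DPC, iDPC and DQE

The in-focus differential phase contrast (DPC) curve is built from the
antisymmetric in-focus PCTF combined over detector half planes. We weight
each pixel by its tilt component (the centre-of-mass limit of the
segmented difference) rather than by sign alone: with tilt weighting the
lens-centroid identity
$\int_{\mathrm{lens}}\Theta_x\,d^2\Theta=\pi\alpha^2\mathcal L\cdot\omega/2$
makes the integrated-DPC (iDPC) curve *exactly* the overlap envelope
$\mathcal L(\omega/\alpha)$ — the stated shape identity between iDPC and
the tcBF damping envelope — whereas plain sign weighting misses it by
20–30%. The closed form is $2(\omega/\alpha)\mathcal L(\omega/\alpha)$ for
DPC; `ctf_dpc_numeric()` provides the quadrature cross-check.

Detective quantum efficiency follows the squared-CTF convention under a
noise power spectrum normalized to 1: `dqe_curves()` returns
$|\mathrm{CTF}|^2/\mathrm{NPS}^2$ for tcBF and DPC, and the iDPC DQE as the
two-component average of the DPC DQEs (the 1/ω integration amplifies
signal and noise identically, so iDPC inherits the DPC DQE). The practical
consequence reproduced by the curves: a suitably defocused tcBF
acquisition transfers low and mid frequencies more efficiently than
in-focus iDPC, which wins only near the aperture cutoff.

For specimens thicker than the depth of field, `ctf_thickness_averaged()`
averages the tcBF CTF over a uniform defocus ramp spanning the thickness;
high frequencies damp on the per-frequency depth-of-field scale
Δz ≈ λ/ω².

# Mean free paths, thickness and dose efficiency

An energy-filtered image decays as
$I(t)=I_0\,e^{-t/\lambda_{HA}}e^{-t/\lambda_{in}}$ — the second factor is
inelastic scattering, the first the high-angle elastic scattering that
misses the detector even without an objective aperture. With
$\lambda_{HA}=a\,\lambda_{in}$ (a ≈ 46 for the modelled geometry) the
combined constant is $\lambda_{in}' = \frac{a}{a+1}\lambda_{in}$ = 0.979
λ_in, i.e. 303 nm for ice. Thickness estimation inverts the decay,
t = −λ ln(fraction); the default uses the uncorrected λ_in (the
convention of the collection-efficiency analysis this package models), the
λ_in′ correction is opt-in. An unfiltered bright-field signal instead
decays with the elastic mean free path λ_el, fitted by `fit_elastic_mfp()`
as a through-origin least-squares line of ln(fraction) against −t: the
intercept is pinned because a zero-thickness specimen retains everything,
and with only a handful of specimens a free intercept is unidentifiable.
The ratio of the two channels grows as $e^{t/\lambda_{\mathrm{eff}}}$ with
$1/\lambda_{\mathrm{eff}} = 1/\lambda_{in} - 1/\lambda_{el}$ ≈ 1/495 nm —
the dose advantage of unfiltered tcBF over EFTEM: ~2× at 400 nm, ~3× at
550 nm, ~5× at 800 nm.

# The forward simulator

`simulate_datacube()` implements a single-slice forward model: exit wave
= probe × object transmission $a(r)e^{i\phi(r)}$, pattern = squared
modulus of its Fourier transform, box-binned from the phantom's reciprocal
grid to the detector grid (binning factor b, detector pixel
Δα = b·λ/(N·pixel)), Poisson-sampled at the configured dose. Design
choices:

* **Dose** is electrons per Å², so a pattern expects dose·Δd² counts; the
  CBED is normalized by Parseval so counts book-keep to the transmitted
  fraction within 0.5%.
* **Randomness**: each scan position draws from a stream seeded by
  (seed, position index), so patterns are reproducible regardless of
  evaluation order.
* **Attenuation/inelastic channel** (optional): the coherent pattern is
  scaled by $e^{-t/\lambda_{el}}$ and a fraction $1-e^{-t/\lambda_{in}}$
  is re-added after a Gaussian angular blur of configurable width (the
  measured inelastic angular scales are a small fraction of a mrad, far
  below the aperture). How much elastic contrast survives into the
  inelastic channel is physically uncertain, so it is an explicit
  `preserved_contrast` parameter rather than a hard-wired assumption.
* **Centre conventions**: the reciprocal-space origin sits at floor(N/2)
  (0-based) after fftshift throughout, and the detector centre is stored
  as a fractional pixel coordinate.

What the simulator deliberately does **not** model: multislice/dynamical
scattering, frozen-phonon thermal scattering, detector MTF and readout
noise, beam-induced motion and scan distortion. Passing tests therefore
establish the *algorithmic* correctness of the reconstruction chain and
the internal consistency of the transfer theory, not robustness to those
experimental effects.

## Phantoms and band limitation

`make_phantom()` generates three families: gold-on-carbon-style strong
phase disks (optionally carrying a sinusoidal lattice at a configurable
spacing, each disk at a random orientation so the power spectrum shows a
ring), paired membrane ridges, and point grids. Two parameters exist
because of a real property of this imaging mode: a single detector pixel
transfers information to 2α (~2 Å here) while the scan samples at Δd
(8–16 Å), so any phantom content between those scales is *aliased* in the
virtual images. Aliased content is exactly what upsampling later recovers,
but it also decorrelates and biases cross-correlation registration. The
phantom therefore exposes `background_sigma_A` and `disk_edge_sigma_A`;
the parameter-recovery study conditions soften disk rims at the scan step
(σ = Δd), while the upsampling conditions keep the lattice sharp — the
recovered ring *is* the aliased content. A phantom can also carry an
absorption channel (`amplitude_contrast`, modelling intensity scattered to
high angles by the strong scatterers): this matters at exact focus, where
a pure weak-phase object produces *no* bright-field contrast
(sin χ = 0) and shift measurement on a phase-only phantom would be
degenerate rather than zero. The in-focus study condition uses
amplitude_contrast = 0.5; defocused conditions use pure phase.

# The reconstruction algorithm

## Disk detection and masks

`find_bf_disk()` thresholds the scan-averaged pattern at half its robust
(99th-percentile) maximum, takes the intensity-weighted centroid and
equivalent-area radius, and down-weights a configurable rim annulus.
`shift_measurement_mask()` widens the exclusion to the annulus of width
λ/(2Δd) in detector angle plus half a pixel: for pixels inside it, every
frequency the scan can sample lies in the triple-overlap region, so their
virtual image is an exactly shifted copy of the axial image. Rim pixels
violate this — part of their in-band content has single-sideband
(complex-CTF) transfer — and we measured the resulting shift bias at up to
+7% of the defocus at 0.5 µm before adopting the rule. The full disk is
still used for the final summation, with shifts regularized by the fitted
aberration surface.

## Shift measurement

Registration is cross-correlation with a local upsampled-DFT refinement
(default 1/16 pixel; ties broken toward the smaller shift by the local
search). The reference is the axial-pixel image first, then the running
shift-corrected mean (default 3 iterations, tolerance 0.05 scan pixels);
the axial pixel is pinned to zero shift each iteration. Weights are
normalized correlation-peak heights. Three options matter at low dose and
form the documented low-dose configuration (used in the finite-dose test
conditions): `filter = "cross"` — fully whitened phase correlation
amplifies empty-band noise and fails below roughly 20 counts per detector
pixel; a Gaussian low-pass of ~0.8 scan pixels; and `det_smooth = 2`,
which registers each pixel from the average of its 5×5 detector
neighbourhood. The parallax shift changes by only Δf·Δα (fractions of a
scan pixel) between neighbours, so the neighbourhood average costs
negligible shift blur and buys a ~25× gain in counting statistics — the
same angular-resolution-for-SNR trade that motivates binning detectors in
practice.

## Aberration fitting and regularization

`fit_aberration_surface()` solves the weighted linear model
$W = -(1/k_0)\nabla_\Theta\chi$: defocus contributes ΔfΘ, twofold
astigmatism $(a\Theta_x+b\Theta_y,\; b\Theta_x-a\Theta_y)$, and an
optional third-order spherical term $C_3|\Theta|^2\Theta$. Defocus +
astigmatism is the default order — coma-level terms are only worth fitting
when the acquisition is known to carry them. `regularize_shifts()` either
replaces the measured field by the model prediction or blends by
registration confidence; replacement is what the reconstruction pipeline
uses by default at finite dose, mirroring the practice of regularizing
measured shift fields by the probe aberration function.

## Upsampled summation

`reconstruct_tcbf()` accumulates every masked pixel's virtual-image
samples on a grid refined by the integer factor s, at positions corrected
by −W, with a Gaussian kernel (σ = 0.6 fine pixels), divides by the
accumulated kernel mass (a kernel-density estimate over the sub-pixel
shift distribution), and deconvolves the kernel response exactly in
Fourier space (gain-limited at 20×). Two implementation notes:

* The division by the accumulated coverage is what restores super-Nyquist
  information: each single-pixel image is band-limited to the scan
  Nyquist, and any linear recombination of shifted copies stays
  band-limited; only the locally-normalized (nonlinear) density estimate
  recovers the finer structure that the ensemble of sub-pixel offsets
  encodes.
* A fixed interpolation kernel imprints its MTF on the result; a bilinear
  kernel at the fine-grid scale costs up to ~20% of in-band power at
  s = 2. The Gaussian-kernel + exact-deconvolution pair removes this
  (in-band agreement with the s = 1 reference is ≤3% at s = 8, 0.1% at
  s = 2). At s = 1 no kernel is used at all: the sum applies exact
  sub-pixel Fourier phase-ramp shifts.

The recommended bound s ≤ α/Δα (beyond which single-pixel blur δ = Δα·Δf
exceeds the fine pixel) produces a warning, not an error. The function
also returns the uncorrected sum (all shifts zero; zero-pad Fourier
upsampled onto the same grid when s > 1) for the before/after comparison,
and the coverage map.

`radial_power_spectrum()` normalizes by the pixel count so profiles from
different sampling rates are directly comparable; the upsampling test
checks that a phantom lattice ring beyond the scan Nyquist appears in the
s = 8 reconstruction at ≥5× its local background while the in-band profile
matches the s = 1 reconstruction within 5%.

`dpc_images()` forms tilt-weighted (default) or sign-weighted half-plane
difference images and integrates them to iDPC by Fourier division by
i(kx + i ky) with the DC bin zeroed — consistent with the tilt-weighted
transfer-curve convention above.

# Study conditions and problem sizes

The test and acceptance suites run entirely on simulated data at the
following scales, chosen to exercise the claims at desk scale:

* Parameter recovery: 256² phantom (1 Å pixels), 32×32 scan at 8 Å,
  48×48 detector, α = 4 mrad at 300 kV, dose 100 e⁻/Å²
  (~14 e⁻ per bright-field detector pixel), Δf ∈ {0, 0.5, 1, 2} µm.
  Recovered defocus is within 2% (typically <1%), shift magnitudes are
  linear in |Θ| with R² > 0.99, and the in-focus field stays below 0.1
  scan pixels.
* Upsampling: same geometry with α = 5.5 mrad, a 5 Å lattice (between the
  s = 8 recoverable limit of 2 Å and the 16 Å scan Nyquist), dose
  200 e⁻/Å², upsample s = 8.
* Transfer-theory oracles: 512-point curves, 256-sample quadratures,
  three defocus values.
* Unit tests use a faster 128²-phantom, 16×16-scan configuration.

# Numerical choices and degenerate inputs

* Quadratures use linear fractional-area antialiasing at disk rims; 256
  samples across the diameter give ~3×10⁻⁵ envelope accuracy.
* iDPC at ω = 0 is the finite ω→0⁺ limit (L(0) = 1) for curves; in images
  the DC bin of the Fourier division is zeroed.
* Registration on an all-flat cube raises a degenerate-registration error
  (relative flatness below 10⁻¹⁰); non-convergence returns the last
  iterate with a message, not an error.
* Thickness inversion masks (NA) non-positive fractions and rejects
  fractions above 1; λ_eff requires λ_el > λ_in.
* The kernel deconvolution gain is floored at 0.05 to bound noise
  amplification at the corners of the fine-grid band.
* Zero-coverage fine-grid cells (possible when regularized shift fields
  quantize onto a sublattice) are filled from the locally smoothed density
  ratio; occupied cells keep their exact values.

# Limitations

* Single-slice optics: no multislice or dynamical scattering, so the
  thickness-dependent contrast attenuation is modelled only through the
  exponential mean-free-path channel, and the thickness-averaged CTF is an
  approximation valid for uniform specimens.
* No detector MTF, readout noise, scan distortion or beam-induced motion;
  experimental shift fields will be noisier and can carry non-optical
  terms the aberration model does not absorb.
* The registration accuracy floor is set by phantom content between the
  scan band and the optical limit (aliasing); real specimens always
  contain such content, which is why the aberration-surface
  regularization, not the raw measured field, feeds the final summation.
* The elastic-MFP fit assumes a single exponential; beyond roughly one
  elastic mean free path multiple scattering converts phase contrast to
  amplitude contrast and the model progressively loses meaning.
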