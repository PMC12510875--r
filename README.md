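# tcbfstem

Tilt-corrected bright-field STEM (tcBF-STEM) for thick, weakly scattering
biological specimens, in R.

Cryo-EM of thick samples (intact bacteria, organelles, sections beyond
~500 nm) loses an exponentially growing fraction of its electrons to
inelastic scattering. Energy-filtered TEM (EFTEM) discards those electrons;
tcBF-STEM keeps them. A defocused probe is scanned across the specimen
while a pixelated detector records the full convergent-beam pattern at
every position (4D-STEM). Each detector pixel inside the bright-field disk
acts as its own tilted-illumination bright-field microscope: under defocus
Δf its scan image is displaced by the parallax shift

    W(Θ) = Δf · Θ

where Θ is the pixel's detector angle. Measuring those shifts by
cross-correlation, fitting them with the gradient of the lens aberration
function, undoing them and summing restores a single sharp, dose-efficient
image — and because the shifts are known to sub-scan-pixel precision, the
sum can be accumulated on a finer grid than the scan itself, recovering
information beyond the scan Nyquist limit.

The package is aimed at electron microscopists and methods developers who
want to plan, simulate, or analyse such acquisitions without experimental
data: every input can be generated by the built-in forward simulator.

## What is implemented

* **Transfer theory** — the tilted-beam phase-contrast transfer function
  PCTF(ω, Θ), the closed-form tcBF CTF
  `CTF(ω) = −L(ω/α)·sin(½ k₀ Δf ω²)` with the disk-overlap envelope
  `L(u) = (2/π)[cos⁻¹(u/2) − (u/2)√(1−u²/4)]`, its half-disk quadrature
  oracle, in-focus DPC/iDPC curves, detective quantum efficiency (DQE)
  comparisons, double/triple overlap-region classification, and
  thickness-averaged CTFs.
* **Mean-free-path model** — high-angle-corrected inelastic mean free path
  λ_in′ = a/(a+1)·λ_in, effective path 1/λ_eff = 1/λ_in − 1/λ_el, the
  exp(t/λ_eff) dose advantage, thickness maps t = −λ ln(I/I₀) from
  energy-filtered fractions, and elastic-MFP fitting from unfiltered decay.
* **Forward simulator** — weak/strong-phase phantoms (gold-on-carbon style
  disks with an optional lattice, membrane ridge pairs, point grids),
  aberrated probes, single-slice CBED formation, detector binning, Poisson
  noise with per-position streams, inelastic angular blur and attenuation.
* **Parallax reconstruction** — bright-field disk detection, per-pixel
  virtual imaging, sub-pixel shift measurement (cross/phase correlation
  with upsampled-DFT refinement and iterative reference refinement),
  aberration-surface fitting (defocus, astigmatism, optional spherical
  term), shift regularization, and kernel-density upsampled summation with
  before/after comparison, plus DPC/iDPC images from the same datacube.
* **Acquisition design** — probe blur 2αΔf, gap-free step bound √2·αΔf,
  maximum useful upsampling α/Δα, depth of field 2λ/α², diffraction-limited
  probe size 0.61λ/α, information-limit periods, and upsampling speed-up.
* **I/O + CLI** — a binary+JSON datacube container, MRC mode-2 and 16-bit
  TIFF images, YAML run configurations, and a `tcbf` command-line tool
  (`inst/cli/tcbf`) with `simulate`, `reconstruct`, `ctf`, `dqe`,
  `thickness` and `design` subcommands.

## Worked example

```r
library(tcbfstem)

cfg <- optical_config(300, alpha = 5.5e-3)      # 300 kV, 5.5 mrad
design_report(300, 5.5e-3, 0.385e-3, 1.3e4, 8)  # plan the acquisition
```

```
<design_report> 300 kV, alpha 5.50 mrad, defocus 1300 nm
  probe blur 2*alpha*df       : 14.3 nm
  pixel blur dalpha*df        : 5.00 A
  gap-free max step           : 101.1 A
  uniform-dose step           : <= 71.5 A
  max useful upsampling       : 14.3
  depth of field 2L/a^2       : 130.2 nm
  probe size 0.61L/a          : 2.18 A
  info limit (1a / 2a)        : 3.58 / 1.79 A
  scan Nyquist period         : 16.0 A
```

An 8 Å scan step therefore samples far below the 101 Å gap-free bound: the
patterns overlap heavily and the surplus can be used for upsampling (up to
~14×). The information-limit periods say the optics transfer to 3.6 Å with
the axial aperture and 1.8 Å using the full bright-field disk.

Signal retention in thick ice, from the mean-free-path model:

```r
m <- mfp_model(lambda_in = 310, a_HA = 46, lambda_el = 830)
m
dose_advantage(550, m$lambda_eff)
```

```
<mfp_model> lambda_in = 310 nm (a_HA = 46 -> 303.4 nm corrected)  lambda_el = 830 nm  lambda_eff = 494.8 nm
[1] 3.04
```

— an unfiltered bright-field image keeps about 3× more signal than an
energy-filtered one at 550 nm thickness.

Simulate a small acquisition and recover its defocus from the measured
parallax field:

```r
cfg4 <- optical_config(300, alpha = 4e-3)
obj <- make_phantom("gold_on_carbon", size = 128, pixel_size = 2, seed = 1,
                    params = list(disk_edge_sigma_A = 8,
                                  lattice_amplitude = 0,
                                  background_sigma_A = 16))
sim <- sim_config(cfg4, aberration_surface(defocus = 7000),
                  scan_shape = c(16, 16), scan_step = 16,
                  detector_shape = c(32, 32), dose = 100, seed = 1)
cube <- simulate_datacube(obj, sim)
sh  <- measure_shifts(cube, shift_measurement_mask(cube),
                      filter = "cross", lowpass = 0.8)
fit <- fit_aberration_surface(sh, cfg4)
fit
rec <- reconstruct_tcbf(cube, regularize_shifts(sh, fit, "replace"),
                        upsample_factor = 2)
rec
```

```
<aberration_fit> defocus 6965.0 A, A1 23.0 A @ 35.1 deg; residual RMS 1.480 A
<tcbf_reconstruction> 32 x 32 @ 8.000 A (upsample 2), 345 detector px
```

The 7000 Å set defocus is recovered to 0.5% from a 100 e⁻/Å² exposure, and
the shift-corrected sum is returned on a grid twice as fine as the scan.

The same pipeline is available from the shell:

```sh
inst/cli/tcbf simulate --defocus-nm 700 --scan-step-angstrom 8 --out cube.dc4
inst/cli/tcbf reconstruct --in cube.dc4 --upsample 4 --regularize replace \
    --out-image rec.mrc --out-report report.json
inst/cli/tcbf ctf --mode tcbf --alpha-mrad 5.5 --defocus-nm 700 --out ctf.csv
```

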