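Package: tcbfstem
Title: Tilt-Corrected Bright-Field STEM Simulation, Reconstruction and Transfer Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dose-efficient imaging of thick, weakly scattering
    biological specimens by tilt-corrected bright-field scanning transmission
    electron microscopy (tcBF-STEM). Provides a forward simulator of
    defocused-probe 4D-STEM datacubes (weak-phase phantoms, aberrated probes,
    Poisson noise, inelastic angular blur), the parallax reconstruction
    algorithm (per-detector-pixel virtual imaging, sub-pixel shift measurement
    with iterative reference refinement, aberration-surface fitting, and
    shift-corrected upsampled summation beyond the scan Nyquist limit),
    analytic contrast-transfer and detective-quantum-efficiency curves for
    tilted-beam bright field, DPC and iDPC imaging, mean-free-path thickness
    estimation from energy-filtered image fractions, and an
    acquisition-design calculator. File I/O covers a binary+JSON datacube
    container, MRC mode-2 and 16-bit TIFF images, and a command-line
    interface ties simulation, reconstruction and analysis into a
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
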