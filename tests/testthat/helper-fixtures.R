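# Shared fixtures. Simulated cubes are cached per test run because several
# tests interrogate the same acquisition.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, fixture_cache)) assign(key, builder(), fixture_cache)
  get(key, fixture_cache)
}

# Band-limited phantom suitable for registration tests: rim-softened disks,
# smooth background, no lattice.
recovery_phantom <- function(size = 256, pixel_size = 1, seed = 3,
                             amplitude_contrast = 0) {
  make_phantom("gold_on_carbon", size = size, pixel_size = pixel_size,
               seed = seed,
               params = list(n_disks = 10, disk_radius_A = 25,
                             lattice_amplitude = 0, disk_edge_sigma_A = 8,
                             background_rms = 0.05, background_sigma_A = 10,
                             amplitude_contrast = amplitude_contrast))
}

# measurement settings for finite-dose acquisitions: unwhitened correlation
# with a mild low-pass, detector-neighbourhood averaging, fine sub-pixel
# refinement
low_dose_opts <- list(max_iter = 3, filter = "cross", lowpass = 0.8,
                      det_smooth = 2, xcorr_upsample = 32)

# Small, fast cube for parallax unit tests: 16x16 scan, 32x32 detector.
# In-focus cubes get an absorptive phantom: a pure weak-phase object is
# invisible at exact focus, so the zero-defocus check needs the amplitude
# channel.
small_cube <- function(defocus = 7000, dose = Inf, seed = 5,
                       alpha = 4e-3) {
  key <- sprintf("cube_%g_%g_%d_%g", defocus, dose, seed, alpha)
  cached(key, function() {
    cfg <- optical_config(300, alpha)
    obj <- recovery_phantom(size = 128, pixel_size = 2, seed = 3,
                            amplitude_contrast = if (defocus == 0) 0.5 else 0)
    sim <- sim_config(cfg, aberration_surface(defocus = defocus),
                      scan_shape = c(16, 16), scan_step = 16,
                      detector_shape = c(32, 32), dose = dose, seed = seed)
    suppressWarnings(simulate_datacube(obj, sim))
  })
}

# Study-condition cube for acceptance tests: 32x32 scan, 48x48 detector.
study_cube <- function(defocus, dose = 100, seed = 11, alpha = 4e-3) {
  key <- sprintf("study_%g_%g_%d_%g", defocus, dose, seed, alpha)
  cached(key, function() {
    cfg <- optical_config(300, alpha)
    phantom <- recovery_phantom(
      amplitude_contrast = if (defocus == 0) 0.5 else 0)
    sim <- sim_config(cfg, aberration_surface(defocus = defocus),
                      scan_shape = c(32, 32), scan_step = 8,
                      detector_shape = c(48, 48), dose = dose, seed = seed)
    suppressWarnings(simulate_datacube(phantom, sim))
  })
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
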