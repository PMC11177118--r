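# Shared small fixtures. Everything is generated in code; no data files.

# Small acquisition geometry used throughout the unit tests: 64 time bins at
# the 12.5 ns (80 MHz) period, 96-pixel frames.
small_config <- function(image_size = 96, n_time_bins = 64) {
  acquisition_config(n_time_bins = n_time_bins, image_size = image_size,
                     irf_center_ns = 2, irf_fwhm_ns = 0.3)
}

# High-resolution geometry for closed-form phasor comparisons, where
# time-discretization error must sit below 1e-6.
fine_config <- function(n_time_bins = 4096) {
  acquisition_config(n_time_bins = n_time_bins, image_size = 2,
                     irf_center_ns = 2, irf_fwhm_ns = 0.3)
}

# Calibration phasor from a simulated noiseless IRF frame (32x32 > 500 px).
make_cal <- function(config) {
  calibration_from_irf(make_irf(config, total_photons = 1e6,
                                frame = c(32, 32)))
}

# Calibrated phasor (complex scalar) of a noiseless uniform-fraction decay.
calibrated_phasor_of <- function(fraction, species, config,
                                 photons = 1e4) {
  d <- simulate_decay(matrix(fraction, 2, 2), species,
                      irf_histogram_of(config), photons, config,
                      noisy = FALSE)
  ph <- calibrate(phasor_transform(d), make_cal(config))
  complex(real = ph$g[1, 1], imaginary = ph$s[1, 1])
}

# Independent AUC oracle: Mann-Whitney U statistic with midrank ties.
auc_oracle <- function(scores, truth) {
  truth <- as.logical(truth)
  r <- rank(scores)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
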