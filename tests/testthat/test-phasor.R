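# Phasor transform, calibration, semicircle utilities, chord projection.

test_that("phasor of simple histograms matches hand-computed values", {
  f <- 0.08                             # 80 MHz in 1/ns
  D <- 1 / f
  # all counts at t = 0
  expect_equal(phasor_of_histogram(c(5, 0, 0), c(0, 1, 2), f), 1 + 0i)
  # two photons at t = 0 and t = D/4: (1 + i)/2
  expect_equal(phasor_of_histogram(c(1, 1), c(0, D / 4), f), 0.5 + 0.5i,
               tolerance = 1e-12)
  # counts uniform over a full period: first harmonic vanishes
  cfg <- acquisition_config(n_time_bins = 64, image_size = 1)
  expect_equal(Mod(phasor_of_histogram(rep(3, 64), bin_times(cfg), f)), 0,
               tolerance = 1e-12)
})

test_that("phasor_transform agrees with the brute-force complex sum", {
  cfg <- small_config(image_size = 6)
  d <- simulate_decay(matrix(runif(36), 6, 6), nadh_species(),
                      irf_histogram_of(cfg), 800, cfg, seed = 4)
  ph <- phasor_transform(d)
  tp <- bin_times(cfg)
  f <- harmonic_freq(cfg)
  for (idx in list(c(1, 1), c(3, 5), c(6, 6))) {
    z <- phasor_of_histogram(d$counts[idx[1], idx[2], ], tp, f)
    expect_equal(ph$g[idx[1], idx[2]], Re(z), tolerance = 1e-12)
    expect_equal(ph$s[idx[1], idx[2]], Im(z), tolerance = 1e-12)
  }
})

test_that("zero-count pixels inside the mask are flagged", {
  cfg <- acquisition_config(n_time_bins = 4, image_size = 2)
  counts <- array(1, c(2, 2, 4))
  counts[1, 1, ] <- 0
  expect_warning(ph <- phasor_transform(decay_image(counts, cfg)),
                 "zero-count")
  expect_true(is.na(ph$g[1, 1]))
  expect_false(ph$mask[1, 1])
  expect_true(all(ph$mask[-1]))
})

test_that("calibration phasor: pooling, delta positions, pixel floor", {
  cfg <- acquisition_config(n_time_bins = 128, image_size = 32,
                            irf_center_ns = 0.05, irf_fwhm_ns = 0)
  f <- harmonic_freq(cfg)
  irf <- make_irf(cfg, 1e6, frame = c(32, 32))
  cal <- calibration_from_irf(irf)
  # delta at t0: z_IT = exp(i 2 pi f t0) with t0 the center of the hit bin
  k <- 1 + floor(0.05 / 12.5 * 128)
  t0 <- bin_times(cfg)[k]
  expect_equal(cal$z, exp(1i * 2 * pi * f * t0), tolerance = 1e-12)
  # photon weighting: identical pixels pool to the same phasor as one pixel
  one <- phasor_of_histogram(irf$counts[1, 1, ], bin_times(cfg), f)
  expect_equal(cal$z, one, tolerance = 1e-12)
  # fewer than 500 pixels is rejected
  expect_error(calibration_from_irf(make_irf(cfg, 1e4, frame = c(10, 10))),
               "500")
})

test_that("calibration removes the IRF regardless of its center and width", {
  f <- 0.08
  for (irf_par in list(c(1, 0.2), c(6, 0.8), c(3, 0))) {
    cfg <- acquisition_config(n_time_bins = 4096, image_size = 2,
                              irf_center_ns = irf_par[1],
                              irf_fwhm_ns = irf_par[2])
    z <- calibrated_phasor_of(1, nadh_species(), cfg)
    expect_equal(Mod(z - phasor_of_lifetime(0.4, f)), 0, tolerance = 1e-6)
  }
  # identity calibration and self-calibration
  cfg <- small_config(image_size = 2)
  cal <- make_cal(cfg)
  expect_equal(calibrate(0.3 + 0.2i, 1 + 0i), 0.3 + 0.2i)
  expect_equal(calibrate(cal$z, cal), 1 + 0i, tolerance = 1e-12)
  expect_error(calibrate(0.5 + 0i, 0 + 0i), "modulus")
})

test_that("semicircle map and phase-lifetime inversion round-trip", {
  f <- 0.08
  expect_equal(phasor_of_lifetime(0, f), 1 + 0i)
  expect_equal(phasor_of_lifetime(Inf, f), 0 + 0i)
  z <- phasor_of_lifetime(0.4, f)
  expect_equal(Re(z), 0.9611, tolerance = 5e-4)
  expect_equal(Im(z), 0.1933, tolerance = 5e-4)

  expect_equal(lifetime_from_phasor(1 + 0i, f), 0)
  expect_equal(lifetime_from_phasor(phasor_of_lifetime(3.5, f), f), 3.5,
               tolerance = 1e-12)
  expect_equal(lifetime_from_phasor(0.5 + 0.5i, f), 1.98944,
               tolerance = 1e-5)
  expect_warning(out <- lifetime_from_phasor(-0.1 + 0.2i, f), "undefined")
  expect_true(is.na(out))
})

test_that("phasor ratio is the normalized orthogonal chord projection", {
  f <- 0.08
  refs <- reference_pair(nadh_species(), f)
  expect_equal(phasor_ratio(refs$z_short, refs), 1)
  expect_equal(phasor_ratio(refs$z_long, refs), 0)

  # noiseless mixtures project to their exact fraction (affine-exact)
  for (fr in seq(-1, 2, by = 0.25)) {
    p <- fr * refs$z_short + (1 - fr) * refs$z_long
    expect_equal(phasor_ratio(p, refs), fr, tolerance = 1e-12)
  }

  # displacement perpendicular to the chord does not change r
  mid <- 0.5 * (refs$z_short + refs$z_long)
  chord <- refs$z_short - refs$z_long
  perp <- complex(real = -Im(chord), imaginary = Re(chord)) / Mod(chord)
  expect_equal(phasor_ratio(mid + 0.07 * perp, refs), 0.5, tolerance = 1e-12)

  # r strictly increases along the chord from z_long to z_short
  rs <- phasor_ratio(refs$z_long + seq(0, 1, 0.1) * chord, refs)
  expect_true(all(diff(rs) > 0))

  expect_error(reference_pair(z_short = 0.5 + 0.2i, z_long = 0.5 + 0.2i),
               "coincident")
})

test_that("reference chord can be recovered from the phasor cloud", {
  cfg <- small_config(image_size = 24, n_time_bins = 256)
  fr <- matrix(runif(24 * 24, 0.15, 0.85), 24, 24)
  d <- simulate_decay(fr, nadh_species(), irf_histogram_of(cfg), 5e4, cfg,
                      seed = 3)
  ph <- calibrate(phasor_transform(d), make_cal(cfg))
  fit <- fit_reference_pair(ph)
  expect_equal(fit$tau_short_ns, 0.4, tolerance = 0.1)
  expect_equal(fit$tau_long_ns, 3.5, tolerance = 0.15)
})
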