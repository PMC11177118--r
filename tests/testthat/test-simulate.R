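# Synthetic TCSPC generator: IRF, decay mixtures, fragments, label channel.

test_that("IRF histogram: delta limit, photon conservation, self-calibration", {
  cfg <- acquisition_config(n_time_bins = 64, image_size = 1,
                            irf_center_ns = 3.1, irf_fwhm_ns = 0)
  irf <- make_irf(cfg, total_photons = 1e4)
  h <- irf$counts[1, 1, ]
  k <- 1 + floor(3.1 / 12.5 * 64)
  expect_equal(h[k], 1e4)               # delta limit: all counts in one bin
  expect_equal(sum(h), 1e4)             # noiseless conservation

  cfgg <- small_config()
  irfg <- make_irf(cfgg, total_photons = 1e6, frame = c(32, 32))
  expect_equal(sum(irfg$counts), 1e6, tolerance = 1e-12)
  # calibrating the IRF against itself yields (1, 0)
  cal <- calibration_from_irf(irfg)
  expect_equal(Mod(calibrate(cal$z, cal) - (1 + 0i)), 0, tolerance = 1e-12)
  # an IRF wider than the period is rejected
  expect_error(acquisition_config(irf_fwhm_ns = 13, period_ns = 12.5),
               "narrower")
})

test_that("noiseless mono-exponential decays hit the closed-form semicircle point", {
  cfg <- fine_config()
  f <- harmonic_freq(cfg)
  for (tau in c(0.4, 3.5)) {
    z <- calibrated_phasor_of(1, species_model(tau, tau + 5, TRUE), cfg)
    expect_equal(Mod(z - phasor_of_lifetime(tau, f)), 0, tolerance = 1e-6)
  }
})

test_that("calibrated mixture phasor is the linear combination of pure phasors", {
  cfg <- small_config(image_size = 2)
  f <- harmonic_freq(cfg)
  sp <- nadh_species()

  # delta-IRF linearity is exact: mixture phasor = f*z_short + (1-f)*z_long
  cfg_d <- acquisition_config(n_time_bins = 64, image_size = 2,
                              irf_center_ns = 2, irf_fwhm_ns = 0)
  z1 <- calibrated_phasor_of(1, sp, cfg_d)
  z0 <- calibrated_phasor_of(0, sp, cfg_d)
  for (fr in c(0.25, 0.5, 0.9)) {
    zm <- calibrated_phasor_of(fr, sp, cfg_d)
    expect_equal(Mod(zm - (fr * z1 + (1 - fr) * z0)), 0, tolerance = 1e-9)
  }

  # Gaussian IRF + calibration: matches the closed-form combination to 1e-3
  # (frozen from the semicircle formula: 0.75 of 0.4 ns + 0.25 of 3.5 ns)
  zm <- calibrated_phasor_of(0.75, sp, small_config(image_size = 2,
                                                    n_time_bins = 256))
  expect_equal(Re(zm), 0.7819, tolerance = 1e-3)
  expect_equal(Im(zm), 0.2523, tolerance = 1e-3)
})

test_that("Poisson draws are seed-reproducible and conserve the mean budget", {
  cfg <- small_config(image_size = 8)
  fr <- matrix(0.6, 8, 8)
  a <- simulate_decay(fr, nadh_species(), irf_histogram_of(cfg), 500, cfg,
                      seed = 99)
  b <- simulate_decay(fr, nadh_species(), irf_histogram_of(cfg), 500, cfg,
                      seed = 99)
  expect_identical(a$counts, b$counts)       # bit-identical under same seed

  noiseless <- simulate_decay(fr, nadh_species(), irf_histogram_of(cfg),
                              500, cfg, noisy = FALSE)
  expect_equal(total_intensity(noiseless),
               matrix(500, 8, 8), tolerance = 1e-9)

  # Poisson totals: mean of >= 100 replicate pixels within 3 sigma
  big <- simulate_decay(matrix(0.6, 10, 10), nadh_species(),
                        irf_histogram_of(cfg), 500, cfg, seed = 7)
  tot <- total_intensity(big)
  expect_lt(abs(mean(tot) - 500), 3 * sqrt(500 / 100))
})

test_that("fragment scenarios set the documented ground-truth states", {
  cfg <- small_config(image_size = 64)
  veh <- make_fragment("vehicle", n_cells = 20, config = cfg, seed = 5)
  expect_true(all(veh$truth$cell_state == "viable"))
  expect_false(any(veh$truth$pi_positive))

  # degenerate rim: no cell is within 0 px of the boundary
  ring0 <- make_fragment("necroptotic_ring", n_cells = 20, config = cfg,
                         seed = 5, rim_px = 0)
  expect_identical(ring0$truth$cell_state, veh$truth$cell_state)

  ring <- make_fragment("necroptotic_ring", n_cells = 30, config = cfg,
                        seed = 6, rim_px = 8)
  expect_true(any(ring$truth$cell_state == "necroptotic"))
  expect_true(any(ring$truth$cell_state == "viable"))

  # rim wider than the fragment: every cell necroptotic, with a warning
  expect_warning(
    allring <- make_fragment("necroptotic_ring", n_cells = 10, config = cfg,
                             seed = 6, rim_px = 1000),
    "rim")
  expect_true(all(allring$truth$cell_state == "necroptotic"))

  apo <- make_fragment("apoptotic", n_cells = 10, config = cfg, seed = 7)
  expect_true(all(apo$truth$cell_state == "apoptotic_necrotic"))
  expect_true(all(apo$truth$pi_positive))
})

test_that("mixed-viability dead counts follow the binomial law", {
  cfg <- small_config(image_size = 128)
  fr <- make_fragment("mixed_viability", n_cells = 200, config = cfg,
                      seed = 123, dead_prob = 0.3)
  dead <- sum(fr$truth$pi_positive)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.3)   # binomial 99% interval
  expect_gte(dead, bounds[1])
  expect_lte(dead, bounds[2])
})

test_that("label channel separates dead and alive cell totals", {
  cfg <- small_config(image_size = 64)
  fr <- make_fragment("mixed_viability", n_cells = 25, config = cfg,
                      seed = 11, dead_prob = 0.4)
  labels <- voronoi_labels(fr$layout$centroids, fr$layout$mask)
  totals <- tapply(fr$pi[labels > 0], labels[labels > 0], sum)
  dead <- fr$truth$pi_positive[as.integer(names(totals))]
  expect_true(all(totals[dead] > 1000))     # Poisson(5000) tail above 1000
  expect_true(all(totals[!dead] <= 100 + 5 * sqrt(100)))

  # photons_alive = 0 gives exactly zero counts in viable cells
  pi0 <- simulate_label_channel(fr$layout, fr$truth, photons_dead = 5000,
                                photons_alive = 0, seed = 2)
  tot0 <- tapply(pi0[labels > 0], labels[labels > 0], sum)
  expect_true(all(tot0[!dead] == 0))
})
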