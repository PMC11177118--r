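# LMR, KDE distributions, modes, NMS.

test_that("LMR arithmetic, monotonicity and invalid-pixel flagging", {
  expect_equal(lmr(0.5, 0.5), 1.0)
  expect_equal(lmr(0.75, 0.5), 0.5)
  # raising free NAD(P)H lowers LMR; raising free FAD (lower bound-FAD
  # fraction) raises it
  r_n <- seq(0.1, 0.9, 0.1)
  expect_true(all(diff(lmr(r_n, rep(0.5, 9))) < 0))
  expect_true(all(diff(lmr(rep(0.5, 9), r_n)) < 0))
  # denominator guard
  out <- lmr(c(0.5, 0.5), c(0.5, 1e-5))
  expect_true(is.na(out[2]) && !is.na(out[1]))
})

test_that("LMR is invariant to common photon-budget rescaling", {
  cfg <- small_config(image_size = 8)
  cal <- make_cal(cfg)
  r_of <- function(photons, species) {
    d <- simulate_decay(matrix(0.6, 8, 8), species, irf_histogram_of(cfg),
                        photons, cfg, noisy = FALSE)
    phasor_ratio(calibrate(phasor_transform(d), cal),
                 reference_pair(species, harmonic_freq(cfg)))
  }
  l1 <- lmr(r_of(500, nadh_species()), r_of(500, fad_species()))
  l2 <- lmr(r_of(5e4, nadh_species()), r_of(5e4, fad_species()))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("KDE normalizes to unit sum and locates point masses", {
  g <- nms_grid()
  k <- kde(0.25, g)                       # single on-grid value
  expect_equal(sum(k$density), 1, tolerance = 1e-12)
  expect_equal(k$points[which.max(k$density)], 0.25, tolerance = 1e-9)

  # two equal-mass bumps separated by an exact multiple of the grid step
  withr::with_seed(8, {
    v <- rnorm(1500, -0.25, 0.03)
    k2 <- kde(c(v, v + 0.65), g)
  })
  dens <- k2$density
  pk <- which(diff(sign(diff(dens))) == -2) + 1   # interior local maxima
  pk <- pk[order(dens[pk], decreasing = TRUE)][1:2]
  expect_equal(dens[pk[1]], dens[pk[2]], tolerance = 0.02)
  expect_equal(sort(k2$points[pk]), c(-0.25, 0.40), tolerance = 0.02)
})

test_that("distribution mode picks the KDE argmax with low-tie preference", {
  expect_equal(distribution_mode(rep(1.2, 50), lmr_grid()), 1.2,
               tolerance = 1e-9)
  withr::with_seed(2, {
    v <- c(rnorm(900, 1.0, 0.02), rnorm(100, 2.0, 0.02))
  })
  expect_equal(distribution_mode(v, lmr_grid()), 1.0, tolerance = 0.02)
})

test_that("mode of a vehicle-fragment LMR field recovers the generator baseline", {
  cfg <- small_config(image_size = 80)
  fr <- make_fragment("vehicle", n_cells = 40, config = cfg, seed = 31)
  q <- quantify_fragment(fr$nadh, fr$fad,
                         make_irf(cfg, 1e6, frame = c(32, 32)),
                         fr$layout$centroids, pi_image = fr$pi)
  m <- distribution_mode(q$lmr_map[is.finite(q$lmr_map)], lmr_grid())
  # generator baseline: fractions 0.5/0.5 -> LMR = 1, within 2 grid steps
  expect_lt(abs(m - 1), 2 * 5e-3 + 0.05)  # KDE mode of a jittered field
})

test_that("NMS: self-normalization, translation equivariance, null shift", {
  withr::with_seed(5, vals <- rnorm(4000, 1.1, 0.08))
  shifted <- nms(vals, vals)
  expect_lte(abs(distribution_mode(shifted, nms_grid())), 5e-3)

  n1 <- nms(vals, 1.0)
  n2 <- nms(vals + 0.2, 1.0)
  expect_equal(as.numeric(n2 - n1), rep(0.2, length(vals)), tolerance = 1e-12)
  expect_equal(attr(n1, "baseline_mode"), 1.0)
  expect_error(nms(vals, NULL), "baseline")
})

test_that("vehicle fragments show no NMS shift between timepoints", {
  ts <- vehicle_timeseries(timepoints = c(0, 9), n_cells = 40,
                           config = small_config(image_size = 80), seed = 17)
  expect_true(all(abs(ts$median_nms) < 0.05))
})

test_that("NMS concentrates per state in the documented bands", {
  cfg <- small_config(image_size = 96)
  irf <- make_irf(cfg, 1e6, frame = c(32, 32))
  qof <- function(scenario, seed, ...) {
    fr <- make_fragment(scenario, n_cells = 50, config = cfg, seed = seed, ...)
    q <- quantify_fragment(fr$nadh, fr$fad, irf, fr$layout$centroids,
                           pi_image = fr$pi)
    list(q = q, fr = fr)
  }
  veh <- qof("vehicle", 41)
  base_mode <- distribution_mode(veh$q$lmr_map[is.finite(veh$q$lmr_map)],
                                 lmr_grid())

  nms_veh <- veh$q$lmr_map - base_mode
  inband <- nms_veh >= -0.28 & nms_veh <= 0.33
  expect_gt(mean(inband[is.finite(nms_veh)]), 0.9)

  apo <- qof("apoptotic", 42)
  nms_apo <- apo$q$lmr_map - base_mode
  dead_px <- apo$q$labels > 0          # every cell is dead in this scenario
  expect_gt(mean(nms_apo[dead_px & is.finite(nms_apo)] > 0.33), 0.9)

  ring <- qof("necroptotic_ring", 43, rim_px = 10)
  nms_ring <- ring$q$lmr_map - base_mode
  ring_cells <- which(ring$fr$truth$cell_state == "necroptotic")
  ring_px <- ring$q$labels %in% ring_cells
  expect_gt(length(ring_cells), 0)
  expect_gt(mean(nms_ring[ring_px & is.finite(nms_ring)] < -0.28), 0.9)
})
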