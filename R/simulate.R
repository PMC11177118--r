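# Synthetic live-tumor-fragment FLIM data generator.
#
# Decay physics: each pixel's expected histogram is the circular (periodic)
# convolution of the discretized IRF with a bin-integrated two-species
# mono-exponential mixture at an 80 MHz pulse train, Poisson photon noise on
# top. Circular convolution reflects the steady-state periodic excitation:
# tail photons of long lifetimes wrap into the next period instead of being
# truncated, which keeps calibrated mono-exponential phasors on the universal
# semicircle up to O(1/G^2) discretization error.

#' Decay image container
#'
#' Per-pixel photon-count histograms for one spectral channel, stored as a
#' numeric array of dimension (rows, cols, time bins).
#'
#' @param counts Numeric array (H, W, G) of photon counts (a (G)-vector or
#'   (H, W) slice count of 1 is promoted).
#' @param config The [acquisition_config()] the histograms were recorded with.
#' @param channel Optional channel tag ("nadh", "fad", "irf", ...).
#' @return An object of class `decay_image`.
#' @export
decay_image <- function(counts, config, channel = NA_character_) {
  if (is.null(dim(counts))) counts <- array(counts, c(1L, 1L, length(counts)))
  stopifnot(length(dim(counts)) == 3L,
            dim(counts)[3] == config$n_time_bins,
            all(counts >= 0 | is.na(counts)))
  structure(list(counts = counts, config = config, channel = channel),
            class = "decay_image")
}

#' @export
print.decay_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("decay_image [%s]: %d x %d px, %d bins, %.4g photons total\n",
              x$channel, d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' @export
dim.decay_image <- function(x) dim(x$counts)

# Unit-mass discretized Gaussian IRF over one period, wrapped circularly.
# fwhm = 0 collapses to a delta in the bin containing the center.
irf_histogram <- function(config) {
  G <- config$n_time_bins
  D <- config$period_ns
  edges <- seq(0, D, length.out = G + 1L)
  if (config$irf_fwhm_ns == 0) {
    h <- numeric(G)
    h[min(G, 1L + floor(config$irf_center_ns / D * G))] <- 1
    return(h)
  }
  sd <- config$irf_fwhm_ns / (2 * sqrt(2 * log(2)))
  h <- numeric(G)
  for (k in -4:4) { # wrap +-4 periods; Gaussian mass beyond is negligible
    h <- h + diff(stats::pnorm(edges, mean = config$irf_center_ns + k * D,
                               sd = sd))
  }
  h / sum(h)
}

# Bin-integrated, period-wrapped mono-exponential decay weights (sum to 1).
# Integrating the continuous model over each bin (not point sampling) matches
# TCSPC binning and keeps phasors accurate at G as low as 64.
decay_weights <- function(tau_ns, config) {
  stopifnot(tau_ns > 0)
  G <- config$n_time_bins
  D <- config$period_ns
  edges <- seq(0, D, length.out = G + 1L)
  e <- exp(-edges / tau_ns)
  (e[-(G + 1L)] - e[-1L]) / (1 - exp(-D / tau_ns))
}

# As decay_weights, but each bin integrates the wrapped exponential over a
# window CENTERED on the bin's time offset (j-1)*dt, i.e. over
# [(j-1)dt - dt/2, (j-1)dt + dt/2]. Discrete convolution adds time offsets
# (not bin centers), so a convolution kernel must carry its mass centered on
# those offsets; the plain left-edge kernel would shift the convolved signal
# half a bin early (an O(1/G) phasor phase error that IRF calibration cannot
# remove).
decay_weights_centered <- function(tau_ns, config) {
  stopifnot(tau_ns > 0)
  G <- config$n_time_bins
  D <- config$period_ns
  dt <- D / G
  edges <- (seq_len(G + 1L) - 1.5) * dt            # from -dt/2, period-wrapped
  cdf <- function(t) {                             # periodic-extended CDF
    k <- floor(t / D)
    tm <- t - k * D
    k + (1 - exp(-tm / tau_ns)) / (1 - exp(-D / tau_ns))
  }
  diff(cdf(edges))
}

# Circular convolution of two equal-length histograms via FFT.
circ_convolve <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) /
    length(a)
  pmax(out, 0)
}

# Expected unit-mass measured histogram: the IRF-convolved decay, computed on
# an oversampled circular time grid and re-integrated into the G acquisition
# bins. Convolving at the acquisition resolution would compose two half-bin
# offsets (an O(1/G) phase error that calibration cannot remove); convolving
# at `oversample` sub-bins keeps the bin-centered phasor of the result within
# O(1/G^2) of the continuous value, so IRF calibration recovers the universal
# semicircle point. A coarse IRF histogram is treated as piecewise-constant
# within each bin (mass-preserving upsampling).
measured_histogram <- function(irf, tau_ns, config, oversample = 8L) {
  G <- config$n_time_bins
  fine_cfg <- acquisition_config(n_time_bins = G * oversample,
                                 period_ns = config$period_ns,
                                 image_size = 1L,
                                 irf_center_ns = config$irf_center_ns,
                                 irf_fwhm_ns = config$irf_fwhm_ns)
  irf_fine <- rep(irf / sum(irf) / oversample, each = oversample)
  h_fine <- circ_convolve(irf_fine, decay_weights_centered(tau_ns, fine_cfg))
  h <- colSums(matrix(h_fine, oversample, G))
  h / sum(h)
}

#' Simulate an IRF measurement
#'
#' Produces a decay image whose per-pixel histogram is a discretized Gaussian
#' at `irf_center_ns` with width `irf_fwhm_ns` (a delta when the width is 0),
#' emulating instantaneous scattering from a gold-nanoshell reference sample.
#'
#' @param config An [acquisition_config()].
#' @param total_photons Total photon budget across the whole frame (> 0).
#' @param frame Frame size `c(rows, cols)`; default a single pixel. Use e.g.
#'   `c(32, 32)` to obtain the >500 pixels a calibration phasor requires.
#' @param noisy If TRUE, per-pixel counts are Poisson draws around the
#'   expectation; if FALSE (default) the exact expectation is returned.
#' @param seed Optional seed for the noisy variant.
#' @return A [decay_image()] with channel tag "irf".
#' @examples
#' cfg <- acquisition_config(n_time_bins = 64)
#' irf <- make_irf(cfg, total_photons = 1e4)
#' sum(irf$counts)
#' @export
make_irf <- function(config, total_photons, frame = c(1L, 1L), noisy = FALSE,
                     seed = NULL) {
  stopifnot(total_photons > 0, length(frame) == 2L, all(frame >= 1L))
  h <- irf_histogram(config) * total_photons / prod(frame)
  counts <- aperm(array(h, c(config$n_time_bins, frame[1], frame[2])),
                  c(2, 3, 1))
  if (noisy) {
    draw <- function() array(stats::rpois(length(counts), counts),
                             dim(counts))
    counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  decay_image(counts, config, channel = "irf")
}

#' Simulate a two-species decay image
#'
#' Per pixel, the expected histogram is
#' `photons * circconv(irf, f * w_short + (1 - f) * w_long)` where `w_short`
#' and `w_long` are unit-mass bin-integrated mono-exponential decays at the
#' species lifetimes and `f` is the per-pixel INTENSITY fraction of the
#' short-lifetime species. The circular convolution is evaluated on an
#' oversampled time grid and re-integrated into the acquisition bins (see
#' the package vignette), so calibrated phasors of simulated decays match
#' closed-form semicircle points to O(1/G^2). Counts are Poisson-drawn
#' unless `noisy = FALSE`.
#'
#' @param fractions Matrix (H, W) of short-species intensity fractions in
#'   \[0, 1\], or a scalar (interpreted as a 1 x 1 image unless `dims` given).
#' @param species A [species_model()].
#' @param irf IRF histogram: a numeric vector of length G, or a
#'   [decay_image()] (pooled over pixels). Normalized internally.
#' @param photons_per_pixel Expected total photons per pixel (> 0); scalar or
#'   matrix conformal with `fractions`.
#' @param config An [acquisition_config()].
#' @param noisy Poisson noise toggle (default TRUE).
#' @param seed Optional seed; the same seed reproduces bit-identical counts.
#' @param dims Optional `c(H, W)` used when `fractions` is scalar.
#' @param channel Channel tag for the output.
#' @return A [decay_image()].
#' @examples
#' cfg <- acquisition_config(n_time_bins = 128, image_size = 4)
#' d <- simulate_decay(matrix(0.75, 4, 4), nadh_species(),
#'                     irf_histogram_of(cfg), 1e4, cfg, noisy = FALSE)
#' sum(d$counts[1, 1, ])
#' @export
simulate_decay <- function(fractions, species, irf, photons_per_pixel, config,
                           noisy = TRUE, seed = NULL, dims = NULL,
                           channel = species$channel) {
  if (is.null(dim(fractions)))
    fractions <- matrix(fractions,
                        nrow = if (is.null(dims)) 1L else dims[1],
                        ncol = if (is.null(dims)) length(fractions) else dims[2])
  stopifnot(all(fractions >= 0 & fractions <= 1),
            all(photons_per_pixel > 0))
  if (inherits(irf, "decay_image"))
    irf <- apply(irf$counts, 3, sum)
  stopifnot(length(irf) == config$n_time_bins, sum(irf) > 0)
  irf <- irf / sum(irf)

  hs <- measured_histogram(irf, species$tau_short_ns, config)
  hl <- measured_histogram(irf, species$tau_long_ns, config)
  f <- as.vector(fractions)
  expected <- outer(f, hs) + outer(1 - f, hl)     # n_px x G, rows sum to 1
  expected <- expected * as.vector(photons_per_pixel * (fractions * 0 + 1))

  G <- config$n_time_bins
  counts <- if (noisy) {
    draw <- function() stats::rpois(length(expected), as.vector(expected))
    v <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    array(v, c(dim(fractions), G))
  } else {
    array(as.vector(expected), c(dim(fractions), G))
  }
  decay_image(counts, config, channel = channel)
}

#' Unit-mass IRF histogram of a configuration
#'
#' Convenience accessor for the discretized (wrapped) Gaussian IRF the
#' configuration describes, normalized to total mass 1.
#'
#' @param config An [acquisition_config()].
#' @return Numeric vector of length `n_time_bins` summing to 1.
#' @export
irf_histogram_of <- function(config) irf_histogram(config)

# ---------------------------------------------------------------------------
# Fragment layout helpers

# Disk-shaped fragment support mask centered in the frame.
fragment_mask <- function(image_size, radius = floor(image_size * 0.42)) {
  ctr <- (image_size + 1) / 2
  d2 <- outer((seq_len(image_size) - ctr)^2,
              (seq_len(image_size) - ctr)^2, "+")
  d2 <= radius^2
}

# Dart-throwing centroid sampler with a relaxing minimum-separation rule,
# guaranteeing exactly n distinct in-mask centroids.
sample_centroids <- function(mask, n) {
  px <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(px) >= n)
  min_sep <- 0.75 * sqrt(nrow(px) / n)
  repeat {
    ord <- sample.int(nrow(px))
    kept <- matrix(0, 0, 2)
    for (i in ord) {
      p <- px[i, ]
      if (nrow(kept) == 0 ||
          min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= min_sep^2) {
        kept <- rbind(kept, p)
        if (nrow(kept) == n) break
      }
    }
    if (nrow(kept) == n) break
    min_sep <- min_sep * 0.8
  }
  unname(kept)
}

# Minimum distance from each centroid to the mask boundary (pixels of the
# mask with a 4-neighbour outside the mask or on the frame edge).
boundary_distance <- function(centroids, mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  bnd <- which(mask & !inner, arr.ind = TRUE)
  apply(centroids, 1, function(p)
    sqrt(min((bnd[, 1] - p[1])^2 + (bnd[, 2] - p[2])^2)))
}

#' Simulate a live-tumor-fragment dataset
#'
#' Builds a disk-shaped fragment mask densely packed with `n_cells` cells,
#' assigns per-cell death states according to `scenario`, renders per-pixel
#' short-species fraction maps (piecewise constant per Voronoi cell plus
#' Gaussian jitter), and simulates NAD(P)H and FAD decay cubes plus a
#' propidium-iodide-like label channel.
#'
#' Scenarios:
#' \describe{
#'   \item{vehicle}{all cells viable at baseline fractions.}
#'   \item{apoptotic, necrotic}{all cells in the apoptotic/necrotic state
#'     (decreased free NAD(P)H, raising LMR and NMS).}
#'   \item{necroptotic_ring}{cells within `rim_px` of the mask boundary become
#'     necroptotic (free NAD(P)H raised to the post-treatment target);
#'     interior cells stay viable. A rim wider than the fragment makes every
#'     cell necroptotic, with a warning.}
#'   \item{mixed_viability}{each cell is apoptotic/necrotic with probability
#'     `dead_prob`, otherwise viable.}
#' }
#'
#' @param scenario One of "vehicle", "apoptotic", "necrotic",
#'   "necroptotic_ring", "mixed_viability".
#' @param n_cells Number of cells (>= 1).
#' @param config An [acquisition_config()]; `image_size` sets the frame.
#' @param seed Integer seed; the full dataset is reproducible under it.
#' @param effects A [fragment_effects()] with per-state target fractions.
#' @param nadh,fad [species_model()]s for the two channels.
#' @param photons_per_pixel Expected raw photons per in-mask pixel
#'   (default 800, about 1e4 after 5x5 binning).
#' @param background_photons Expected photons per out-of-mask pixel
#'   (default 3, far below the n > 20 intensity threshold).
#' @param dead_prob Death probability for `mixed_viability` (default 0.3).
#' @param rim_px Necroptotic rim depth in pixels for `necroptotic_ring`.
#' @param pi_photons_dead,pi_photons_alive Label-channel budgets passed to
#'   [simulate_label_channel()].
#' @return A list of class `flim_fragment` with elements `nadh`, `fad`
#'   ([decay_image()]s), `pi` (intensity matrix), `layout` (mask, centroids,
#'   cell_state), `truth` (frac_short maps, cell_state, pi_positive) and
#'   `config`.
#' @export
make_fragment <- function(scenario = c("vehicle", "apoptotic", "necrotic",
                                       "necroptotic_ring", "mixed_viability"),
                          n_cells, config, seed = NULL,
                          effects = fragment_effects(),
                          nadh = nadh_species(), fad = fad_species(),
                          photons_per_pixel = 800, background_photons = 3,
                          dead_prob = 0.3, rim_px = 12,
                          pi_photons_dead = 5000, pi_photons_alive = 100) {
  scenario <- match.arg(scenario)
  stopifnot(n_cells >= 1)
  build <- function() {
    mask <- fragment_mask(config$image_size)
    centroids <- sample_centroids(mask, n_cells)

    state <- rep("viable", n_cells)
    if (scenario %in% c("apoptotic", "necrotic")) {
      state[] <- "apoptotic_necrotic"
    } else if (scenario == "necroptotic_ring" && rim_px > 0) {
      ring <- boundary_distance(centroids, mask) <= rim_px
      if (all(ring))
        warning("rim covers the whole fragment: all cells necroptotic")
      state[ring] <- "necroptotic"
    } else if (scenario == "mixed_viability") {
      state[stats::runif(n_cells) < dead_prob] <- "apoptotic_necrotic"
    }

    # Per-cell target fractions with biological cell-to-cell jitter.
    targets <- t(vapply(state, function(s) effects[[s]], numeric(2)))
    targets <- targets +
      matrix(stats::rnorm(2 * n_cells, 0, effects$cell_jitter_sd), n_cells)
    targets <- pmin(pmax(targets, 0.01), 0.99)

    labels <- voronoi_labels(centroids, mask)
    jit <- function(col) {
      m <- matrix(0.5, nrow(mask), ncol(mask)) # out-of-mask value, unused
      inm <- labels > 0
      m[inm] <- targets[labels[inm], col] +
        stats::rnorm(sum(inm), 0, effects$pixel_jitter_sd)
      pmin(pmax(m, 0.005), 0.995)
    }
    f_nadh <- jit(1)
    f_fad <- jit(2)

    photons <- matrix(background_photons, nrow(mask), ncol(mask))
    photons[mask] <- photons_per_pixel

    layout <- list(mask = mask, centroids = centroids, cell_state = state)
    truth <- list(frac_short_nadh = f_nadh, frac_short_fad = f_fad,
                  cell_state = state, pi_positive = state != "viable")
    irf <- irf_histogram(config)
    list(nadh = simulate_decay(f_nadh, nadh, irf, photons, config),
         fad = simulate_decay(f_fad, fad, irf, photons, config),
         pi = simulate_label_channel(layout, truth,
                                     photons_dead = pi_photons_dead,
                                     photons_alive = pi_photons_alive),
         layout = layout, truth = truth, config = config,
         scenario = scenario)
  }
  out <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  structure(out, class = "flim_fragment")
}

#' @export
print.flim_fragment <- function(x, ...) {
  cat(sprintf("flim_fragment [%s]: %d cells (%d dead), %d x %d px\n",
              x$scenario, length(x$truth$cell_state),
              sum(x$truth$pi_positive), nrow(x$layout$mask),
              ncol(x$layout$mask)))
  invisible(x)
}

#' Simulate an extrinsic death-label (PI-like) intensity channel
#'
#' Dead cells receive a Poisson photon budget concentrated around the nucleus
#' centroid (Gaussian footprint within the cell's Voronoi region); viable
#' cells receive a uniform low background over their region. With the default
#' budgets, dead-cell totals sit far above and viable-cell totals far below
#' the 1000-count death threshold.
#'
#' @param layout Fragment layout: list with `mask`, `centroids`, `cell_state`.
#' @param truth Ground truth: list with logical `pi_positive` per cell.
#' @param photons_dead Expected total photons deposited in a dead cell
#'   (must exceed `photons_alive`).
#' @param photons_alive Expected total photons in a viable cell (>= 0;
#'   0 yields exactly zero counts).
#' @param nucleus_sd Gaussian footprint SD (pixels) of the dead-cell signal.
#' @param seed Optional seed.
#' @return Integer intensity matrix of the frame size.
#' @export
simulate_label_channel <- function(layout, truth, photons_dead = 5000,
                                   photons_alive = 100, nucleus_sd = 2,
                                   seed = NULL) {
  stopifnot(photons_dead > photons_alive, photons_alive >= 0)
  build <- function() {
    mask <- layout$mask
    labels <- voronoi_labels(layout$centroids, mask)
    lambda <- matrix(0, nrow(mask), ncol(mask))
    for (i in seq_len(nrow(layout$centroids))) {
      px <- which(labels == i, arr.ind = TRUE)
      if (nrow(px) == 0) next
      if (truth$pi_positive[i]) {
        c0 <- layout$centroids[i, ]
        w <- exp(-((px[, 1] - c0[1])^2 + (px[, 2] - c0[2])^2) /
                   (2 * nucleus_sd^2))
        lambda[px] <- photons_dead * w / sum(w)
      } else if (photons_alive > 0) {
        lambda[px] <- photons_alive / nrow(px)
      }
    }
    matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
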