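# Configuration containers and package-wide defaults.
#
# All times are in nanoseconds, frequencies in 1/ns (so 0.08 = 80 MHz).
# Pixel coordinates are 1-based (row, col), the R convention.

#' Acquisition configuration
#'
#' Describes the TCSPC recording geometry used both by the simulator and by
#' the phasor transform: the number of time bins per pixel histogram, the
#' decay record period (12.5 ns, i.e. an 80 MHz pulse train), the frame size,
#' and the instrument response function (IRF) shape.
#'
#' @param n_time_bins Number of histogram time bins per pixel (>= 2).
#' @param period_ns Decay record period D in ns; the first-harmonic phasor
#'   frequency is `1/period_ns` (default 12.5 ns, 80 MHz).
#' @param image_size Frame side length in pixels.
#' @param irf_center_ns IRF peak position within the period, ns.
#' @param irf_fwhm_ns IRF full width at half maximum, ns (0 = delta).
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `acquisition_config`.
#' @examples
#' cfg <- acquisition_config(n_time_bins = 64, image_size = 128)
#' bin_times(cfg)[1:4]
#' @export
acquisition_config <- function(n_time_bins = 256L, period_ns = 12.5,
                               image_size = 512L, irf_center_ns = 2,
                               irf_fwhm_ns = 0.3, seed = NULL) {
  n_time_bins <- as.integer(n_time_bins)
  stopifnot(n_time_bins >= 2L, period_ns > 0, image_size >= 1L,
            irf_fwhm_ns >= 0, irf_center_ns >= 0, irf_center_ns < period_ns)
  if (irf_fwhm_ns >= period_ns)
    stop("irf_fwhm_ns must be narrower than the period")
  structure(list(n_time_bins = n_time_bins, period_ns = period_ns,
                 image_size = as.integer(image_size),
                 irf_center_ns = irf_center_ns, irf_fwhm_ns = irf_fwhm_ns,
                 seed = seed),
            class = "acquisition_config")
}

#' Histogram bin-center times
#'
#' @param config An [acquisition_config()].
#' @return Numeric vector of bin-center times t_p in ns, length `n_time_bins`.
#' @export
bin_times <- function(config) {
  (seq_len(config$n_time_bins) - 0.5) * config$period_ns / config$n_time_bins
}

#' First-harmonic phasor frequency (1/ns)
#'
#' @param config An [acquisition_config()].
#' @return The repetition/harmonic frequency `1/period_ns` in 1/ns.
#' @export
harmonic_freq <- function(config) 1 / config$period_ns

#' Two-species decay model for one spectral channel
#'
#' Autofluorescence decays are modeled as an intensity-weighted mixture of a
#' short- and a long-lifetime mono-exponential. For NAD(P)H the short species
#' is the unbound (free) form (about 0.4 ns vs 3.5 ns bound); for FAD the
#' opposite holds, the protein-bound form being short-lived.
#'
#' @param tau_short_ns,tau_long_ns Lifetimes of the two species (ns),
#'   `0 < tau_short_ns < tau_long_ns`.
#' @param short_is_free TRUE when the short-lifetime species is the unbound
#'   one (NAD(P)H), FALSE when it is the bound one (FAD).
#' @param channel Channel tag, e.g. "nadh" or "fad".
#' @return An object of class `species_model`.
#' @export
species_model <- function(tau_short_ns, tau_long_ns, short_is_free,
                          channel = NA_character_) {
  stopifnot(tau_short_ns > 0, tau_short_ns < tau_long_ns,
            is.logical(short_is_free))
  structure(list(tau_short_ns = tau_short_ns, tau_long_ns = tau_long_ns,
                 short_is_free = short_is_free, channel = channel),
            class = "species_model")
}

#' @rdname species_model
#' @export
nadh_species <- function() species_model(0.4, 3.5, TRUE, "nadh")

#' @rdname species_model
#' @details FAD pure-species lifetimes are configurable defaults
#'   (0.3 ns bound, 2.8 ns free), literature-typical values; every downstream
#'   quantity depends only on the configured references.
#' @export
fad_species <- function() species_model(0.3, 2.8, FALSE, "fad")

#' Preprocessing configuration
#'
#' @param min_photons Photon-count threshold on the summed NAD(P)H intensity;
#'   pixels are kept only when strictly above it (default 20).
#' @param kernel_size_nadh,kernel_size_fad Side length of the circular binning
#'   kernel per channel (defaults 5 and 6).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(min_photons = 20, kernel_size_nadh = 5L,
                              kernel_size_fad = 6L) {
  stopifnot(min_photons >= 0, kernel_size_nadh >= 1, kernel_size_fad >= 1)
  structure(list(min_photons = min_photons,
                 kernel_size_nadh = as.integer(kernel_size_nadh),
                 kernel_size_fad = as.integer(kernel_size_fad)),
            class = "preprocess_config")
}

#' Segmentation configuration
#'
#' @param max_region_px Voronoi regions with strictly more pixels are excluded
#'   from single-cell analysis (default 1000); guards against regions that are
#'   mostly non-cellular space.
#' @param pi_dead_counts A cell is marked dead when its total label-channel
#'   (PI) photon count is strictly above this value (default 1000). The
#'   threshold is intensity-based and experiment-dependent; it is deliberately
#'   a plain configuration field.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(max_region_px = 1000L, pi_dead_counts = 1000) {
  stopifnot(max_region_px > 0, pi_dead_counts > 0)
  structure(list(max_region_px = as.integer(max_region_px),
                 pi_dead_counts = pi_dead_counts),
            class = "segmentation_config")
}

#' NMS tri-state classification bands
#'
#' Cells with mean NMS below `t_left` are called necroptotic, within
#' `[t_left, t_right]` (both endpoints inclusive) viable, and above `t_right`
#' apoptotic/necrotic. Defaults are the cross-validated operating points
#' -0.28 and 0.33.
#'
#' @param t_left,t_right Band edges, `t_left < t_right`.
#' @param note Free-text provenance note carried in reports.
#' @return An object of class `threshold_bands`.
#' @export
threshold_bands <- function(t_left = -0.28, t_right = 0.33,
                            note = "default cross-validated operating points") {
  stopifnot(!is.na(t_left), !is.na(t_right), t_left < t_right)
  structure(list(t_left = t_left, t_right = t_right, note = note),
            class = "threshold_bands")
}

#' Per-state target species fractions for the fragment simulator
#'
#' All values are SHORT-lifetime-species intensity fractions per channel
#' (free NAD(P)H; bound FAD). Vehicle defaults are 0.5/0.5 so the baseline
#' LMR sits at 1. The apoptotic/necrotic state lowers the free-NAD(P)H
#' fraction and the bound-FAD fraction (cell-mean NMS approximately +0.75);
#' the necroptotic state raises free NAD(P)H to 0.75 (cell-mean NMS
#' approximately -0.55).
#'
#' @param viable_nadh,viable_fad Baseline short-species fractions.
#' @param apoptotic_nadh,apoptotic_fad Fractions for apoptotic/necrotic cells.
#' @param necroptotic_nadh,necroptotic_fad Fractions for necroptotic cells.
#' @param cell_jitter_sd Per-cell Gaussian jitter of the target fraction.
#' @param pixel_jitter_sd Per-pixel Gaussian jitter within a cell.
#' @return An object of class `fragment_effects`.
#' @export
fragment_effects <- function(viable_nadh = 0.5, viable_fad = 0.5,
                             apoptotic_nadh = 0.30, apoptotic_fad = 0.40,
                             necroptotic_nadh = 0.75, necroptotic_fad = 0.55,
                             cell_jitter_sd = 0.03, pixel_jitter_sd = 0.015) {
  vals <- c(viable_nadh, viable_fad, apoptotic_nadh, apoptotic_fad,
            necroptotic_nadh, necroptotic_fad)
  stopifnot(all(vals >= 0 & vals <= 1), cell_jitter_sd >= 0,
            pixel_jitter_sd >= 0)
  structure(list(viable = c(nadh = viable_nadh, fad = viable_fad),
                 apoptotic_necrotic = c(nadh = apoptotic_nadh,
                                        fad = apoptotic_fad),
                 necroptotic = c(nadh = necroptotic_nadh,
                                 fad = necroptotic_fad),
                 cell_jitter_sd = cell_jitter_sd,
                 pixel_jitter_sd = pixel_jitter_sd),
            class = "fragment_effects")
}

# Cell-state vocabulary shared across modules.
CELL_STATES <- c("necroptotic", "viable", "apoptotic_necrotic")

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("acquisition_config: G=%d bins, period=%.4g ns (f=%.4g GHz), %dx%d px, IRF %.3g ns FWHM @ %.3g ns\n",
              x$n_time_bins, x$period_ns, 1 / x$period_ns, x$image_size,
              x$image_size, x$irf_fwhm_ns, x$irf_center_ns))
  invisible(x)
}
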