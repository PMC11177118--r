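# End-to-end quantification: threshold -> bin -> phasor -> calibrate ->
# phasor ratio -> LMR -> NMS -> Voronoi cell statistics; plus the
# screen-scale drivers used for validation.

#' Quantify one fragment: decay cubes to LMR map and cell table
#'
#' Runs the full per-fragment chain: NAD(P)H intensity thresholding (the
#' NAD(P)H mask gates BOTH channels), circular-kernel binning (5x5 NAD(P)H,
#' 6x6 FAD by default), first-harmonic phasor transform, IRF calibration,
#' chord projection to short-species fractions, and the LMR map. Voronoi
#' cells are built from the nucleus centroids, oversized regions excluded,
#' and per-cell mean LMR plus total label-channel intensity aggregated.
#'
#' NMS normalization is left to the caller (it needs a baseline): subtract a
#' baseline mode from `lmr_map` / `cells$mean_lmr` via [nms()], or use
#' [viability_screen()] for population-mode pooling.
#'
#' @param nadh,fad [decay_image()]s of the two channels.
#' @param irf IRF for calibration: a [decay_image()] with >= 500 pixels, a
#'   [calibration_phasor()], or a unit histogram vector (then pooled as one
#'   histogram repeated over 512 nominal pixels). A named list
#'   `list(nadh = , fad = )` gives per-channel calibrations.
#' @param centroids Nucleus centroid matrix (rows: `row`, `col`).
#' @param pi_image Label-channel intensity matrix (or NULL: PI columns 0).
#' @param pre A [preprocess_config()].
#' @param seg A [segmentation_config()].
#' @param nadh_model,fad_model [species_model()]s placing the analytic
#'   reference phasors.
#' @param bands A [threshold_bands()] (cell classes are filled in once NMS is
#'   known; at this stage classes refer to mean LMR and are recomputed by the
#'   callers after normalization).
#' @param fragment_id,timepoint Identifiers carried into the cell table.
#' @return List of class `flim_quant`: `mask`, `r_nadh`, `r_fad`, `lmr_map`,
#'   `labels`, `excluded`, `cells` (with `mean_lmr` column), `refs`
#'   (reference pairs), `cal` (calibration phasors), `f`.
#' @export
quantify_fragment <- function(nadh, fad, irf, centroids, pi_image = NULL,
                              pre = preprocess_config(),
                              seg = segmentation_config(),
                              nadh_model = nadh_species(),
                              fad_model = fad_species(),
                              bands = threshold_bands(),
                              fragment_id = NA, timepoint = NA) {
  cfg <- nadh$config
  f <- harmonic_freq(cfg)

  cal_of <- function(x, channel) {
    if (inherits(x, "calibration_phasor")) return(x)
    if (inherits(x, "decay_image")) return(calibration_from_irf(x))
    # bare histogram: replicate across a nominal 512-pixel pool
    h <- x / sum(x)
    d <- decay_image(aperm(array(h * 1e4, c(cfg$n_time_bins, 32, 16)),
                           c(2, 3, 1)), cfg, channel = "irf")
    calibration_from_irf(d)
  }
  cal <- if (is.list(irf) && !inherits(irf, "decay_image") &&
             !inherits(irf, "calibration_phasor"))
    list(nadh = cal_of(irf$nadh, "nadh"), fad = cal_of(irf$fad, "fad"))
  else { c1 <- cal_of(irf, "irf"); list(nadh = c1, fad = c1) }

  intensity <- total_intensity(nadh)
  mask <- snr_mask(intensity, pre$min_photons)

  quant_channel <- function(decay, kernel, model, calp) {
    binned <- circular_bin(decay, kernel, mask)
    ph <- calibrate(phasor_transform(binned, mask = mask, f = f), calp)
    refs <- reference_pair(model, f)
    list(r = phasor_ratio(ph, refs), refs = refs, phasors = ph)
  }
  qn <- quant_channel(nadh, pre$kernel_size_nadh, nadh_model, cal$nadh)
  qf <- quant_channel(fad, pre$kernel_size_fad, fad_model, cal$fad)

  lmr_map <- lmr(qn$r, qf$r)

  labels <- voronoi_labels(centroids, mask)
  filt <- filter_large_regions(labels, seg$max_region_px)
  if (is.null(pi_image)) pi_image <- matrix(0, nrow(mask), ncol(mask))
  cells <- cell_stats(filt$labels, lmr_map, pi_image, seg,
                      centroids = centroids, bands = bands,
                      fragment_id = fragment_id, timepoint = timepoint)
  names(cells)[names(cells) == "mean_nms"] <- "mean_lmr"
  cells$nms_class <- NULL

  structure(list(mask = mask, intensity = intensity,
                 r_nadh = qn$r, r_fad = qf$r, lmr_map = lmr_map,
                 phasors = list(nadh = qn$phasors, fad = qf$phasors),
                 refs = list(nadh = qn$refs, fad = qf$refs),
                 labels = filt$labels, excluded = filt$excluded,
                 cells = cells, cal = cal, f = f,
                 fragment_id = fragment_id, timepoint = timepoint),
            class = "flim_quant")
}

#' Simulate a multi-fragment viability screen
#'
#' Generates `n_fragments` mixed-viability fragments with per-fragment dead
#' fractions drawn uniformly from `dead_prob_range`, all reproducible under
#' the master seed.
#'
#' @param n_fragments Number of fragments (default 30).
#' @param n_cells Cells per fragment (default 150).
#' @param config An [acquisition_config()].
#' @param seed Master seed; per-fragment seeds are derived from it.
#' @param dead_prob_range Range of per-fragment death probabilities.
#' @param ... Further arguments passed to [make_fragment()].
#' @return List of `flim_fragment` objects; the drawn `dead_prob` is attached
#'   to each as attribute `dead_prob`.
#' @export
simulate_screen <- function(n_fragments = 30L, n_cells = 150L,
                            config = acquisition_config(), seed = NULL,
                            dead_prob_range = c(0, 0.6), ...) {
  draws <- function() list(
    probs = stats::runif(n_fragments, dead_prob_range[1], dead_prob_range[2]),
    seeds = sample.int(.Machine$integer.max, n_fragments))
  dd <- if (is.null(seed)) draws() else withr::with_seed(seed, draws())
  lapply(seq_len(n_fragments), function(i) {
    fr <- make_fragment("mixed_viability", n_cells = n_cells, config = config,
                        seed = dd$seeds[i], dead_prob = dd$probs[i], ...)
    attr(fr, "dead_prob") <- dd$probs[i]
    fr
  })
}

#' Run the population-normalized viability screen analysis
#'
#' Quantifies every fragment, pools the per-cell mean LMR across the whole
#' screen, normalizes by the population KDE mode (`NMS = LMR - mode`),
#' classifies cells with the tri-state bands, and computes the
#' cross-validated AUROC of mean NMS against the label-channel death call,
#' fragment-level dead percentages, and their regression.
#'
#' @param fragments List of `flim_fragment` objects ([simulate_screen()]), or
#'   of precomputed `flim_quant` objects.
#' @param pre,seg,bands,nadh_model,fad_model Pipeline settings.
#' @param irf_photons Photon budget for the shared simulated IRF measurement
#'   used for calibration (synthetic fragments only).
#' @param k,seed Cross-validation folds and fold-assignment seed.
#' @param grid KDE grid for the population LMR mode.
#' @return List of class `flim_screen`: `cells` (pooled table with `mean_lmr`,
#'   `mean_nms`, `nms_class`, `pi_dead`, `truth_dead`), `baseline_mode`,
#'   `cv` ([cv_auroc()] result), `summaries` ([fragment_viability()]),
#'   `regression` ([fragment_regression()]), `confusion`.
#' @export
viability_screen <- function(fragments, pre = preprocess_config(),
                             seg = segmentation_config(),
                             bands = threshold_bands(),
                             nadh_model = nadh_species(),
                             fad_model = fad_species(),
                             irf_photons = 1e6, k = 10L, seed = NULL,
                             grid = lmr_grid()) {
  quants <- lapply(seq_along(fragments), function(i) {
    fr <- fragments[[i]]
    if (inherits(fr, "flim_quant")) return(fr)
    irf <- make_irf(fr$config, total_photons = irf_photons, frame = c(32, 32))
    q <- quantify_fragment(fr$nadh, fr$fad, irf, fr$layout$centroids,
                           pi_image = fr$pi, pre = pre, seg = seg,
                           nadh_model = nadh_model, fad_model = fad_model,
                           bands = bands, fragment_id = i)
    # carry simulator truth for validation when available
    q$cells$truth_dead <- fr$truth$pi_positive[q$cells$cell_id]
    q
  })
  cells <- do.call(rbind, lapply(quants, `[[`, "cells"))
  mode_val <- distribution_mode(cells$mean_lmr, grid)
  cells$mean_nms <- cells$mean_lmr - mode_val
  cells$nms_class <- tri_state(cells$mean_nms, bands)

  cv <- cv_auroc(cells$mean_nms, cells$pi_dead, k = k, seed = seed)
  summaries <- fragment_viability(cells, bands)
  regression <- fragment_regression(summaries)
  confusion <- confusion_metrics(cells$nms_class != "viable", cells$pi_dead)

  structure(list(cells = cells, baseline_mode = mode_val, cv = cv,
                 summaries = summaries, regression = regression,
                 confusion = confusion, bands = bands),
            class = "flim_screen")
}

#' @export
print.flim_screen <- function(x, ...) {
  cat(sprintf("flim_screen: %d fragments, %d cells; baseline LMR mode %.3f\n",
              nrow(x$summaries), nrow(x$cells), x$baseline_mode))
  print(x$cv)
  cat(sprintf("  regression: R^2=%.3f slope=%.3f intercept=%.2f%% p=%.2g\n",
              x$regression$r_squared, x$regression$slope,
              x$regression$intercept, x$regression$p_value))
  invisible(x)
}

#' Vehicle (no-treatment) longitudinal NMS series
#'
#' Simulates one untreated fragment per timepoint under identical generator
#' parameters (fresh noise per timepoint), quantifies each, and normalizes
#' the later timepoints by the mode of the t0 LMR map (per-fragment
#' baseline). Under metabolic homeostasis the NMS distribution should stay
#' centered at zero at every timepoint.
#'
#' @param timepoints Timepoint labels; the first is the baseline t0.
#' @param n_cells,config,seed,... Passed to [make_fragment()].
#' @param pre,seg Pipeline settings.
#' @param grid KDE grid for the baseline mode.
#' @return data.frame with per-timepoint `median_nms`, `mode_nms`,
#'   `pct_dead_nms`, `n_pixels`.
#' @export
vehicle_timeseries <- function(timepoints = c(0, 3, 9), n_cells = 60L,
                               config = acquisition_config(image_size = 96,
                                                           n_time_bins = 64),
                               seed = 1L, pre = preprocess_config(),
                               seg = segmentation_config(),
                               grid = lmr_grid(), ...) {
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max,
                                       length(timepoints)))
  irf <- NULL
  quants <- lapply(seq_along(timepoints), function(i) {
    fr <- make_fragment("vehicle", n_cells = n_cells, config = config,
                        seed = seeds[i], ...)
    if (is.null(irf))
      irf <<- make_irf(config, total_photons = 1e6, frame = c(32, 32))
    quantify_fragment(fr$nadh, fr$fad, irf, fr$layout$centroids,
                      pi_image = fr$pi, pre = pre, seg = seg,
                      timepoint = timepoints[i])
  })
  base_mode <- distribution_mode(quants[[1]]$lmr_map[is.finite(quants[[1]]$lmr_map)],
                                 grid)
  out <- lapply(seq_along(timepoints), function(i) {
    nms_map <- nms(quants[[i]]$lmr_map, base_mode)
    vals <- nms_map[is.finite(nms_map)]
    cells <- quants[[i]]$cells
    cells$mean_nms <- cells$mean_lmr - base_mode
    fv <- fragment_viability(cells)
    data.frame(timepoint = timepoints[i],
               median_nms = stats::median(vals),
               mode_nms = distribution_mode(vals, nms_grid()),
               pct_dead_nms = fv$pct_dead_nms,
               n_pixels = length(vals))
  })
  do.call(rbind, out)
}
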