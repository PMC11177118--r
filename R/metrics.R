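# Lifetime Metabolic Ratio (LMR), kernel density estimates, distribution
# modes, and the Normalized Metabolic Shift (NMS).

#' Lifetime Metabolic Ratio
#'
#' `LMR = (1 - r_nadh) / r_fad`, the ratio of the bound-NAD(P)H intensity
#' fraction to the bound-FAD intensity fraction: `r_nadh` is the
#' short-species (free NAD(P)H) fraction, so `1 - r_nadh` is bound NAD(P)H,
#' and `r_fad` is the short-species (bound FAD) fraction. Increasing bound
#' NAD(P)H or unbound FAD both increase the LMR.
#'
#' @param r_nadh,r_fad Phasor-ratio maps (matrices or vectors of the same
#'   shape) of the short-lifetime species fraction per channel.
#' @param tol Pixels with `|r_fad| < tol` are flagged invalid (NA) rather
#'   than dividing by (near-)zero; default 1e-3.
#' @return LMR values with the shape of the inputs; NA where invalid.
#' @export
lmr <- function(r_nadh, r_fad, tol = 1e-3) {
  stopifnot(length(r_nadh) == length(r_fad))
  out <- (1 - r_nadh) / r_fad
  out[!is.na(r_fad) & abs(r_fad) < tol] <- NA_real_
  out
}

#' Evaluation grid for kernel density estimates
#'
#' Regular grid with the package-wide default spacing of 5e-3.
#'
#' @param lo,hi Grid bounds (`lo < hi`).
#' @param step Grid spacing (default 0.005).
#' @return An object of class `kde_grid` with the grid `points`.
#' @export
kde_grid <- function(lo = -0.5, hi = 1, step = 5e-3) {
  stopifnot(lo < hi, step > 0)
  structure(list(lo = lo, hi = hi, step = step,
                 points = seq(lo, hi, by = step)),
            class = "kde_grid")
}

# Default grids: LMR distributions live on [-0.5, 3], NMS on [-0.5, 1].
#' @rdname kde_grid
#' @export
lmr_grid <- function(step = 5e-3) kde_grid(-0.5, 3, step)

#' @rdname kde_grid
#' @export
nms_grid <- function(step = 5e-3) kde_grid(-0.5, 1, step)

#' Gaussian kernel density estimate on a fixed grid
#'
#' Evaluates a Gaussian KDE on the grid points and renormalizes so the
#' densities SUM to one over the grid (a discrete probability distribution,
#' not a continuous density). Bandwidth defaults to Silverman's rule
#' ([stats::bw.nrd0()]); degenerate samples (single value or zero spread)
#' fall back to one grid step.
#'
#' @param values Numeric sample; must contain at least one finite value.
#' @param grid A [kde_grid()].
#' @param bandwidth Optional kernel SD override.
#' @return The grid object with a `density` field (sums to 1) and the
#'   `bandwidth` used.
#' @export
kde <- function(values, grid = nms_grid(), bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("kde requires at least one finite value")
  if (is.null(bandwidth)) {
    bandwidth <- if (length(values) >= 2 && stats::sd(values) > 0)
      stats::bw.nrd0(values) else grid$step
  }
  n <- length(grid$points)
  dens <- stats::density(values, bw = bandwidth, from = grid$lo, to = grid$hi,
                         n = n)$y
  if (sum(dens) <= 0) { # sample entirely off-grid: place mass at nearest edge
    dens <- rep(0, n)
    dens[if (mean(values) > grid$hi) n else 1L] <- 1
  }
  grid$density <- dens / sum(dens)
  grid$bandwidth <- bandwidth
  grid
}

#' Mode of a distribution via its KDE
#'
#' Grid point maximizing the kernel density estimate; ties are broken toward
#' the lower grid value.
#'
#' @inheritParams kde
#' @return The modal grid value (numeric scalar).
#' @export
distribution_mode <- function(values, grid = lmr_grid(), bandwidth = NULL) {
  k <- kde(values, grid, bandwidth)
  k$points[which.max(k$density)]
}

#' Normalized Metabolic Shift
#'
#' `NMS = LMR(tn) - mode(LMR(t0))`: per-pixel (or per-cell) subtraction of
#' the modal baseline LMR. The baseline mode comes either from the same
#' fragment at its pre-treatment timepoint (`per_fragment_baseline`) or from
#' the pooled single-cell LMR population of a screen (`population_mode`);
#' in both cases the caller supplies the corresponding baseline values (or a
#' precomputed mode).
#'
#' @param lmr_tn LMR values at the timepoint of interest.
#' @param baseline Baseline LMR sample (vector/matrix) from which the mode is
#'   estimated, or a single precomputed mode value.
#' @param grid [kde_grid()] used for the mode (default [lmr_grid()]).
#' @param bandwidth Optional KDE bandwidth.
#' @return NMS values with the shape of `lmr_tn`; the baseline mode used is
#'   attached as attribute `baseline_mode`.
#' @export
nms <- function(lmr_tn, baseline, grid = lmr_grid(), bandwidth = NULL) {
  if (is.null(baseline) || length(baseline) == 0 || all(!is.finite(baseline)))
    stop("missing baseline for NMS normalization")
  mode_val <- if (length(baseline) == 1L) as.numeric(baseline) else
    distribution_mode(baseline, grid, bandwidth)
  stopifnot(is.finite(mode_val))
  out <- lmr_tn - mode_val
  attr(out, "baseline_mode") <- mode_val
  out
}
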