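# First-harmonic phasor transform, IRF calibration, universal-semicircle
# utilities, and the chord projection yielding species fractions.

#' Phasor of a single histogram
#'
#' `z = sum(counts * exp(1i * 2 * pi * f * times)) / sum(counts)` — the
#' first-harmonic Fourier coordinates of a decay histogram.
#'
#' @param counts Non-negative histogram, total > 0.
#' @param times Photon-arrival times of the bins (ns); normally bin centers.
#' @param f Harmonic frequency in 1/ns (0.08 = 80 MHz).
#' @return Complex scalar z; `Re(z) = g`, `Im(z) = s`.
#' @export
phasor_of_histogram <- function(counts, times, f) {
  stopifnot(length(counts) == length(times), sum(counts) > 0)
  sum(counts * exp(1i * 2 * pi * f * times)) / sum(counts)
}

#' Phasor image container
#'
#' @param g,s Real and imaginary phasor parts, (H, W) matrices (NA where
#'   undefined).
#' @param f Harmonic frequency (1/ns).
#' @param mask Logical matrix on which the phasors are defined.
#' @param channel Channel tag.
#' @param calibrated Logical flag.
#' @return An object of class `phasor_image`.
#' @export
phasor_image <- function(g, s, f, mask = NULL, channel = NA_character_,
                         calibrated = FALSE) {
  stopifnot(all(dim(g) == dim(s)))
  if (is.null(mask)) mask <- !is.na(g)
  structure(list(g = g, s = s, f = f, mask = mask, channel = channel,
                 calibrated = calibrated),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("phasor_image [%s]: %d x %d px (%d masked-in), f=%.4g GHz, %s\n",
              x$channel, nrow(x$g), ncol(x$g), sum(x$mask), x$f,
              if (x$calibrated) "calibrated" else "uncalibrated"))
  invisible(x)
}

#' First-harmonic phasor transform of a decay image
#'
#' Computes per pixel `z = sum_p G_p exp(i 2 pi f t_p) / sum_p G_p` with t_p
#' the bin-center times. Pixels outside `mask`, or inside it with zero total
#' counts, get NA phasors; zero-count in-mask pixels additionally raise a
#' warning (they are flagged in the returned mask).
#'
#' @param decay A [decay_image()].
#' @param mask Optional logical matrix restricting the computation.
#' @param f Harmonic frequency; defaults to `1/period_ns` of the
#'   configuration.
#' @return A [phasor_image()] (uncalibrated).
#' @export
phasor_transform <- function(decay, mask = NULL, f = NULL) {
  cfg <- decay$config
  if (is.null(f)) f <- harmonic_freq(cfg)
  d <- dim(decay$counts)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  m <- matrix(decay$counts, d[1] * d[2], d[3])
  tot <- rowSums(m)
  e <- exp(1i * 2 * pi * f * bin_times(cfg))
  z <- as.vector(m %*% e)
  valid <- as.vector(mask) & tot > 0
  if (any(as.vector(mask) & tot <= 0))
    warning("zero-count pixels inside mask: phasor undefined, flagged")
  z <- ifelse(valid, z / ifelse(tot > 0, tot, 1), NA_complex_)
  phasor_image(matrix(Re(z), d[1], d[2]), matrix(Im(z), d[1], d[2]), f,
               mask = matrix(valid, d[1], d[2]), channel = decay$channel)
}

#' Calibration phasor from an IRF measurement
#'
#' Pools the decay histograms of the selected pixels (photon-weighted: the
#' histograms are summed before the transform) and computes the Eq.-style
#' phasor of the pooled histogram. The pooled IRF phasor `z_IT` corresponds
#' to an effective lifetime of 0 ns; at least 500 pixels are required.
#'
#' @param irf_decay A [decay_image()] of the IRF sample.
#' @param pixel_mask Logical matrix selecting pixels (default: all).
#' @param f Harmonic frequency; default from the configuration.
#' @param min_pixels Minimum pixels required (default 500).
#' @return An object of class `calibration_phasor`: fields `z`,
#'   `n_pixels_used`, `f`, `channel`.
#' @export
calibration_from_irf <- function(irf_decay, pixel_mask = NULL, f = NULL,
                                 min_pixels = 500L) {
  cfg <- irf_decay$config
  if (is.null(f)) f <- harmonic_freq(cfg)
  d <- dim(irf_decay$counts)
  if (is.null(pixel_mask)) pixel_mask <- matrix(TRUE, d[1], d[2])
  n <- sum(pixel_mask)
  if (n < min_pixels)
    stop(sprintf("calibration requires > %d pixels, got %d", min_pixels, n))
  m <- matrix(irf_decay$counts, d[1] * d[2], d[3])
  pooled <- colSums(m[as.vector(pixel_mask), , drop = FALSE])
  z <- phasor_of_histogram(pooled, bin_times(cfg), f)
  structure(list(z = z, n_pixels_used = n, f = f,
                 channel = irf_decay$channel),
            class = "calibration_phasor")
}

#' Calibrate phasors against the IRF phasor
#'
#' Complex division `z_cal = z_raw / z_IT` corrects modulation and phase
#' jointly, so a measured zero-lifetime sample maps to (1, 0) and noiseless
#' mono-exponentials land on the universal semicircle.
#'
#' @param phasors A [phasor_image()] or a complex vector of raw phasors.
#' @param cal A [calibration_phasor()] (or a complex scalar `z_IT`).
#' @param tol Rejection tolerance on `|z_IT|`.
#' @return Calibrated phasors, same type as the input.
#' @export
calibrate <- function(phasors, cal, tol = 1e-9) {
  z_it <- if (inherits(cal, "calibration_phasor")) cal$z else cal
  if (!is.finite(Mod(z_it)) || Mod(z_it) < tol)
    stop("calibration phasor has (near-)zero modulus")
  if (is.complex(phasors)) return(phasors / z_it)
  stopifnot(inherits(phasors, "phasor_image"))
  z <- complex(real = phasors$g, imaginary = phasors$s) / z_it
  phasor_image(matrix(Re(z), nrow(phasors$g)), matrix(Im(z), nrow(phasors$g)),
               phasors$f, mask = phasors$mask, channel = phasors$channel,
               calibrated = TRUE)
}

#' Phasor of a mono-exponential lifetime
#'
#' The universal-semicircle map
#' `g = 1 / (1 + (w tau)^2)`, `s = w tau / (1 + (w tau)^2)`, `w = 2 pi f`.
#'
#' @param tau_ns Lifetime(s) in ns (>= 0; Inf maps to the origin).
#' @param f Harmonic frequency (1/ns).
#' @return Complex phasor(s) on the universal semicircle.
#' @export
phasor_of_lifetime <- function(tau_ns, f) {
  stopifnot(all(tau_ns >= 0))
  wt <- 2 * pi * f * tau_ns
  g <- ifelse(is.infinite(wt), 0, 1 / (1 + wt^2))
  s <- ifelse(is.infinite(wt), 0, wt / (1 + wt^2))
  complex(real = g, imaginary = s)
}

#' Phase lifetime of a phasor
#'
#' `tau_phi = s / (g * 2 pi f)`: the exact inverse of
#' [phasor_of_lifetime()] for points on the universal semicircle.
#'
#' @param p Complex phasor(s) or a [phasor_image()].
#' @param f Harmonic frequency (1/ns); taken from a `phasor_image` input.
#' @return Phase lifetime(s) in ns; NA (with a warning) where `g <= 0`.
#' @export
lifetime_from_phasor <- function(p, f = NULL) {
  if (inherits(p, "phasor_image")) {
    if (is.null(f)) f <- p$f
    p <- complex(real = p$g, imaginary = p$s)
  }
  stopifnot(!is.null(f))
  g <- Re(p); s <- Im(p)
  bad <- !is.na(g) & g <= 0
  if (any(bad)) warning("phase lifetime undefined for g <= 0; returning NA")
  out <- s / (g * 2 * pi * f)
  out[bad] <- NA_real_
  out
}

#' Reference pair: pure-species phasors spanning the free/bound chord
#'
#' Builds the two reference phasors either analytically from configured
#' lifetimes (the default) or from explicit phasors. `z_short` is the
#' short-lifetime reference (the phasor-ratio projection equals 1 there) and
#' `z_long` the long-lifetime one (projection 0).
#'
#' @param species A [species_model()], used with `f` to place both references
#'   on the universal semicircle; or NULL when giving phasors directly.
#' @param f Harmonic frequency (1/ns).
#' @param z_short,z_long Optional explicit complex reference phasors.
#' @param tau_short_ns,tau_long_ns Lifetimes recorded with explicit phasors.
#' @return An object of class `reference_pair` with fields `z_short`,
#'   `z_long`, `tau_short_ns`, `tau_long_ns`, `d` (chord length).
#' @export
reference_pair <- function(species = NULL, f = NULL, z_short = NULL,
                           z_long = NULL, tau_short_ns = NA_real_,
                           tau_long_ns = NA_real_) {
  if (!is.null(species)) {
    stopifnot(!is.null(f))
    z_short <- phasor_of_lifetime(species$tau_short_ns, f)
    z_long <- phasor_of_lifetime(species$tau_long_ns, f)
    tau_short_ns <- species$tau_short_ns
    tau_long_ns <- species$tau_long_ns
  }
  d <- Mod(z_short - z_long)
  if (!(d > 0)) stop("coincident reference phasors")
  structure(list(z_short = z_short, z_long = z_long,
                 tau_short_ns = tau_short_ns, tau_long_ns = tau_long_ns,
                 d = d),
            class = "reference_pair")
}

#' Phasor-ratio projection onto the reference chord
#'
#' Orthogonal projection of each phasor onto the line connecting the two
#' pure-species references, normalized so that the long-lifetime reference
#' maps to 0 and the short-lifetime reference to 1:
#' `r = Re((p - z_long) * Conj(z_short - z_long)) / d^2`.
#' For a noiseless mixture, `r` equals the intensity fraction of the
#' short-lifetime species. Shot noise can push `r` slightly outside
#' \[0, 1\]; it is NOT clamped.
#'
#' @param p Complex phasor(s) or a [phasor_image()].
#' @param refs A [reference_pair()].
#' @return Numeric `r` with the shape of the input (matrix for a
#'   `phasor_image`).
#' @export
phasor_ratio <- function(p, refs) {
  stopifnot(inherits(refs, "reference_pair"))
  shape <- NULL
  if (inherits(p, "phasor_image")) {
    shape <- dim(p$g)
    p <- complex(real = p$g, imaginary = p$s)
  }
  chord <- refs$z_short - refs$z_long
  r <- Re((p - refs$z_long) * Conj(chord)) / refs$d^2
  if (!is.null(shape)) r <- matrix(r, shape[1], shape[2])
  r
}

#' Fit the reference chord from the phasor cloud
#'
#' Total-least-squares line (first principal axis) through the calibrated
#' phasor cloud, intersected with the universal semicircle. Provided as an
#' alternative to analytic references when the pure-species lifetimes are to
#' be inferred from the observed linear arrangement of the data; the analytic
#' references remain the default throughout the package.
#'
#' @param phasors A [phasor_image()] (calibrated) or complex vector.
#' @param f Harmonic frequency, for the recorded lifetimes.
#' @return A [reference_pair()] whose references are the two intersections of
#'   the fitted line with the semicircle.
#' @export
fit_reference_pair <- function(phasors, f = NULL) {
  if (inherits(phasors, "phasor_image")) {
    if (is.null(f)) f <- phasors$f
    z <- complex(real = phasors$g[phasors$mask],
                 imaginary = phasors$s[phasors$mask])
  } else z <- phasors
  z <- z[is.finite(Re(z)) & is.finite(Im(z))]
  stopifnot(length(z) >= 2, !is.null(f))
  xy <- cbind(Re(z), Im(z))
  ctr <- colMeans(xy)
  v <- svd(sweep(xy, 2, ctr))$v[, 1]   # TLS direction
  # Intersect {ctr + t v} with circle |z - (0.5, 0)| = 0.5.
  q <- ctr - c(0.5, 0)
  a <- sum(v^2); b <- 2 * sum(q * v); cc <- sum(q^2) - 0.25
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) stop("fitted line does not intersect the universal semicircle")
  t12 <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  pts <- lapply(t12, function(t) ctr + t * v)
  zs <- vapply(pts, function(p) complex(real = p[1], imaginary = p[2]),
               complex(1))
  taus <- vapply(zs, lifetime_from_phasor, numeric(1), f = f)
  i_short <- which.min(taus)
  reference_pair(z_short = zs[i_short], z_long = zs[-i_short][1],
                 tau_short_ns = taus[i_short], tau_long_ns = taus[-i_short][1])
}
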