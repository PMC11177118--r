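# Minimal diagnostic plots (base graphics).

#' Diagnostic phasor-cloud plot
#'
#' Scatter of the (g, s) cloud with the universal semicircle and, optionally,
#' the reference chord overlaid.
#'
#' @param phasors A [phasor_image()].
#' @param refs Optional [reference_pair()] to overlay.
#' @param max_points Subsample cap for dense clouds.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted (g, s) data frame.
#' @export
plot_phasor <- function(phasors, refs = NULL, max_points = 20000, ...) {
  g <- phasors$g[phasors$mask]
  s <- phasors$s[phasors$mask]
  ok <- is.finite(g) & is.finite(s)
  g <- g[ok]; s <- s[ok]
  if (length(g) > max_points) {
    idx <- seq(1, length(g), length.out = max_points)
    g <- g[idx]; s <- s[idx]
  }
  graphics::plot(g, s, pch = ".", col = grDevices::rgb(0, 0, 0, 0.25),
                 xlim = c(0, 1), ylim = c(0, 0.6), xlab = "g", ylab = "s",
                 ...)
  th <- seq(0, pi, length.out = 200)
  graphics::lines(0.5 + 0.5 * cos(th), 0.5 * sin(th), col = "grey40")
  if (!is.null(refs)) {
    graphics::segments(Re(refs$z_long), Im(refs$z_long),
                       Re(refs$z_short), Im(refs$z_short), col = "red3")
    graphics::points(Re(c(refs$z_short, refs$z_long)),
                     Im(c(refs$z_short, refs$z_long)), col = "red3", pch = 19)
  }
  invisible(data.frame(g = g, s = s))
}

#' Plot a KDE distribution with optional classification bands
#'
#' @param k A [kde()] result.
#' @param bands Optional [threshold_bands()] drawn as vertical lines.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_kde <- function(k, bands = NULL, ...) {
  graphics::plot(k$points, k$density, type = "l", xlab = "value",
                 ylab = "probability", ...)
  if (!is.null(bands))
    graphics::abline(v = c(bands$t_left, bands$t_right),
                     col = c("magenta3", "green4"), lty = 2)
  invisible(NULL)
}
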