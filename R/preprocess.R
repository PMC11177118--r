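# Photon-count thresholding and circular-kernel spatial binning.

#' Total photon intensity image
#'
#' Per-pixel sum of the decay histogram over time bins.
#'
#' @param decay A [decay_image()] or a (H, W, G) counts array.
#' @return Numeric (H, W) matrix of summed counts.
#' @export
total_intensity <- function(decay) {
  counts <- if (inherits(decay, "decay_image")) decay$counts else decay
  rowSums(counts, dims = 2L)
}

#' Signal-to-noise pixel mask
#'
#' Keeps pixels whose summed intensity is STRICTLY above `min_photons`
#' (the documented rule is n > 20 on the NAD(P)H intensity; a pixel at
#' exactly the threshold is discarded). The NAD(P)H-derived mask gates both
#' spectral channels.
#'
#' @param intensity Intensity matrix from [total_intensity()].
#' @param min_photons Threshold (default 20).
#' @return Logical matrix, TRUE where the pixel is retained.
#' @export
snr_mask <- function(intensity, min_photons = 20) {
  intensity > min_photons
}

#' Discrete disk footprint of a square kernel
#'
#' Offsets (relative to the anchor pixel) of the disk inscribed in a
#' `kernel_size` x `kernel_size` window. For odd sizes the disk is the set of
#' offsets with squared distance to the center at most ((k-1)/2)^2 (13 pixels
#' at k = 5); for even sizes the window center falls on a half-pixel corner
#' and the threshold is (k/2)^2 - 1, giving the symmetric 24-pixel footprint
#' at k = 6. Sizes 1 and 2 use the full square.
#'
#' @param kernel_size Side length k >= 1.
#' @return Integer matrix with columns `di`, `dj` of row/col offsets.
#' @export
disk_offsets <- function(kernel_size) {
  k <- as.integer(kernel_size)
  stopifnot(k >= 1)
  offs <- seq_len(k) - 1L - ((k - 1L) %/% 2L)
  ctr <- mean(offs)
  r2 <- if (k <= 2L) Inf else if (k %% 2L == 1L) ((k - 1) / 2)^2 else
    (k / 2)^2 - 1
  grid <- expand.grid(di = offs, dj = offs)
  d2 <- (grid$di - ctr)^2 + (grid$dj - ctr)^2
  as.matrix(grid[d2 <= r2 + 1e-9, , drop = FALSE])
}

#' Circular-kernel spatial binning of a decay image
#'
#' Each output pixel's histogram is the SUM (not average) of the input
#' histograms over the disk footprint of [disk_offsets()], restricted to
#' in-mask pixels: masked-out pixels neither receive a binned histogram nor
#' contribute photons to any neighbour. Summing raises per-pixel photon
#' counts, which is the purpose of the step; phasors are count-ratio
#' invariant, so no renormalization is needed.
#'
#' @param decay A [decay_image()].
#' @param kernel_size Kernel side length (>= 1; 1 is the identity).
#' @param mask Logical matrix of retained pixels; default all TRUE.
#' @return A [decay_image()] with binned counts (0 outside the mask).
#' @export
circular_bin <- function(decay, kernel_size, mask = NULL) {
  counts <- decay$counts
  d <- dim(counts)
  if (kernel_size > min(d[1], d[2]))
    stop("kernel larger than image")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(all(dim(mask) == d[1:2]))
  mask3 <- array(rep(mask, d[3]), d)
  if (kernel_size == 1L)
    return(decay_image(counts * mask3, decay$config, decay$channel))
  zeroed <- counts * mask3
  out <- array(0, d)
  for (r in seq_len(nrow(disk <- disk_offsets(kernel_size)))) {
    di <- disk[r, 1]; dj <- disk[r, 2]
    ri <- max(1L, 1L - di):min(d[1], d[1] - di)   # output rows
    rj <- max(1L, 1L - dj):min(d[2], d[2] - dj)
    out[ri, rj, ] <- out[ri, rj, ] + zeroed[ri + di, rj + dj, , drop = FALSE]
  }
  decay_image(out * mask3, decay$config, decay$channel)
}
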