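# Plain-file interchange: decay cubes as multi-page 16-bit TIFF with a JSON
# sidecar, metric maps as float32 TIFF, tables as CSV, manifests as JSON.

#' Write / read a decay image as multi-page TIFF + JSON sidecar
#'
#' One 16-bit page per time bin; counts are rounded to integers on write
#' (values above 65535 are clamped with a warning). The sidecar
#' (`<prefix>.json`) stores the acquisition configuration and channel tag.
#'
#' @param decay A [decay_image()].
#' @param prefix Path prefix; writes `<prefix>.tif` and `<prefix>.json`.
#' @return `write_decay_image()` returns the prefix invisibly;
#'   `read_decay_image()` returns a [decay_image()].
#' @export
write_decay_image <- function(decay, prefix) {
  counts <- round(decay$counts)
  if (any(counts > 65535)) {
    warning("counts above 65535 clamped for 16-bit TIFF")
    counts <- pmin(counts, 65535)
  }
  pages <- lapply(seq_len(dim(counts)[3]),
                  function(p) counts[, , p] / 65535)
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16L)
  cfg <- decay$config
  jsonlite::write_json(
    list(n_time_bins = cfg$n_time_bins, period_ns = cfg$period_ns,
         image_size = cfg$image_size, irf_center_ns = cfg$irf_center_ns,
         irf_fwhm_ns = cfg$irf_fwhm_ns, channel = decay$channel),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_decay_image
#' @export
read_decay_image <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE, as.is = TRUE)
  counts <- array(0, c(dim(pages[[1]]), length(pages)))
  for (p in seq_along(pages)) counts[, , p] <- pages[[p]]
  cfg <- acquisition_config(n_time_bins = meta$n_time_bins,
                            period_ns = meta$period_ns,
                            image_size = meta$image_size,
                            irf_center_ns = meta$irf_center_ns,
                            irf_fwhm_ns = meta$irf_fwhm_ns)
  decay_image(counts, cfg, channel = meta$channel)
}

#' Write / read a real-valued metric map as scaled 32-bit TIFF
#'
#' TIFF integer samples cover \[0, 1\], so the map is affinely rescaled to
#' that range (32-bit precision, ~1e-9 of the value range) with the original
#' range stored in a `<path>.json` sidecar; a second page carries the
#' finite-value mask. Non-finite pixels read back as NaN.
#'
#' @param x Numeric matrix.
#' @param path Output `.tif` path (sidecar written next to it).
#' @return The path invisibly; `read_metric_tiff()` returns the matrix.
#' @export
write_metric_tiff <- function(x, path) {
  fin <- is.finite(x)
  lo <- if (any(fin)) min(x[fin]) else 0
  hi <- if (any(fin)) max(x[fin]) else 1
  span <- if (hi > lo) hi - lo else 1
  scaled <- (x - lo) / span
  scaled[!fin] <- 0
  tiff::writeTIFF(list(scaled, fin * 1), path, bits.per.sample = 32L)
  jsonlite::write_json(list(lo = lo, hi = hi, span = span),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metric_tiff
#' @export
read_metric_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- pages[[1]] * meta$span + meta$lo
  out[pages[[2]] < 0.5] <- NaN
  out
}

#' Centroid table I/O (CSV: cell_id, row, col; 1-based pixel coordinates)
#'
#' @param centroids Matrix or data.frame of `(row, col)` per cell.
#' @param path CSV path.
#' @return Path invisibly; `read_centroids()` returns the centroid matrix.
#' @export
write_centroids <- function(centroids, path) {
  df <- data.frame(cell_id = seq_len(nrow(centroids)),
                   row = centroids[, 1], col = centroids[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[order(df$cell_id), c("row", "col")])
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed, package version, and md5 checksums of the
#' listed input files, so a rerun with an identical manifest is guaranteed to
#' reproduce identical numeric outputs.
#'
#' @param path Output JSON path.
#' @param config Named list (or config objects) to record.
#' @param seed Seed used for the run.
#' @param inputs Character vector of input file paths to checksum.
#' @param extra Optional named list of extra fields.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character(), extra = list()) {
  checks <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  man <- c(list(package = "flimNMS",
                version = as.character(utils::packageVersion("flimNMS")),
                seed = seed,
                config = lapply(config, unclass),
                input_md5 = checks),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}
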