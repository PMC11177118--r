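# Voronoi single-cell partition from nucleus centroids, region filtering,
# and per-cell aggregation of the metabolic metric and label intensity.

#' Voronoi labels from nucleus centroids
#'
#' Assigns every in-mask pixel to its nearest centroid (Euclidean distance
#' between pixel centers); out-of-mask pixels are labeled 0. Ties are broken
#' toward the lowest centroid index. The tessellation is bounded by the
#' fragment mask (not geodesic: distance is measured through space, but only
#' in-mask pixels are assigned), which prevents cells from bleeding into
#' empty space; set `mask = NULL` for a frame-bounded tessellation.
#'
#' @param centroids Numeric matrix with one `(row, col)` centroid per row
#'   (1-based pixel coordinates); at least one centroid must be in the mask.
#' @param mask Logical matrix, or NULL for the full frame (requires `dims`).
#' @param dims Frame size `c(rows, cols)` when `mask` is NULL.
#' @return Integer label matrix (0 = background).
#' @export
voronoi_labels <- function(centroids, mask = NULL, dims = NULL) {
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  if (nrow(centroids) < 1) stop("at least one centroid is required")
  if (is.null(mask)) {
    stopifnot(!is.null(dims))
    mask <- matrix(TRUE, dims[1], dims[2])
  }
  h <- nrow(mask); w <- ncol(mask)
  inm <- which(mask)
  ci <- cbind(round(pmin(pmax(centroids[, 1], 1), h)),
              round(pmin(pmax(centroids[, 2], 1), w)))
  if (!any(mask[ci])) stop("no centroid lies inside the mask")
  rows <- ((inm - 1L) %% h) + 1L
  cols <- ((inm - 1L) %/% h) + 1L
  best <- rep(Inf, length(inm))
  lab <- integer(length(inm))
  for (i in seq_len(nrow(centroids))) {
    d2 <- (rows - centroids[i, 1])^2 + (cols - centroids[i, 2])^2
    upd <- d2 < best          # strict: earlier (lower) index wins ties
    best[upd] <- d2[upd]
    lab[upd] <- i
  }
  out <- matrix(0L, h, w)
  out[inm] <- lab
  out
}

#' Exclude oversized Voronoi regions
#'
#' Regions with STRICTLY more than `max_region_px` pixels are dropped from
#' analysis (relabeled 0) and reported; a 1000-pixel region is retained, a
#' 1001-pixel one excluded. Oversized regions typically contain large
#' stretches of non-cellular space.
#'
#' @param labels Integer label matrix from [voronoi_labels()].
#' @param max_region_px Strict upper pixel bound (default 1000).
#' @return List with `labels` (filtered matrix) and `excluded`
#'   (data.frame `cell_id`, `n_pixels` of the dropped regions).
#' @export
filter_large_regions <- function(labels, max_region_px = 1000L) {
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes > max_region_px)
  out <- labels
  out[out %in% drop] <- 0L
  list(labels = out,
       excluded = data.frame(cell_id = drop,
                             n_pixels = sizes[drop]))
}

#' Per-cell statistics table
#'
#' For each retained Voronoi region: the mean of the metric image over pixels
#' where the metric is finite, the TOTAL label-channel (PI) intensity over
#' ALL region pixels, the strict `> pi_dead_counts` death call, and the
#' tri-state NMS class. Cells with no valid metric pixel are dropped with a
#' warning.
#'
#' @param labels Filtered label matrix ([filter_large_regions()]).
#' @param nms_image Metric matrix aligned with `labels` (normally the NMS
#'   map; any per-pixel metric can be aggregated).
#' @param pi_image Label-channel intensity matrix aligned with `labels`.
#' @param config A [segmentation_config()].
#' @param centroids Optional centroid matrix, carried into the table.
#' @param bands A [threshold_bands()] for the `nms_class` column.
#' @param fragment_id,timepoint Optional identifiers carried into the table.
#' @return A `data.frame` (cell table) with columns `cell_id`, `row`, `col`,
#'   `n_pixels`, `mean_nms`, `total_pi_counts`, `pi_dead`, `nms_class`,
#'   `fragment_id`, `timepoint`.
#' @export
cell_stats <- function(labels, nms_image, pi_image,
                       config = segmentation_config(), centroids = NULL,
                       bands = threshold_bands(), fragment_id = NA,
                       timepoint = NA) {
  stopifnot(all(dim(labels) == dim(nms_image)),
            all(dim(labels) == dim(pi_image)))
  ids <- sort(unique(labels[labels > 0]))
  lab_v <- as.vector(labels)
  keep <- lab_v > 0
  n_px <- tabulate(lab_v[keep])
  pi_tot <- as.vector(tapply(as.vector(pi_image)[keep], lab_v[keep], sum))
  valid <- keep & is.finite(as.vector(nms_image))
  mean_nms <- rep(NA_real_, max(ids))
  if (any(valid)) {
    agg <- tapply(as.vector(nms_image)[valid], lab_v[valid], mean)
    mean_nms[as.integer(names(agg))] <- agg
  }
  tab <- data.frame(
    cell_id = ids,
    row = if (is.null(centroids)) NA_real_ else centroids[ids, 1],
    col = if (is.null(centroids)) NA_real_ else centroids[ids, 2],
    n_pixels = n_px[ids],
    mean_nms = mean_nms[ids],
    total_pi_counts = pi_tot[match(ids, sort(unique(lab_v[keep])))],
    stringsAsFactors = FALSE)
  tab$pi_dead <- tab$total_pi_counts > config$pi_dead_counts
  tab$nms_class <- tri_state(tab$mean_nms, bands)
  tab$fragment_id <- fragment_id
  tab$timepoint <- timepoint
  if (anyNA(tab$mean_nms)) {
    warning(sprintf("%d cell(s) without valid metric pixels dropped",
                    sum(is.na(tab$mean_nms))))
    tab <- tab[!is.na(tab$mean_nms), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
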