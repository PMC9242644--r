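#' Match ROIs between the 445 and 488 channel images
#'
#' One-to-one matching of ROI centroids across channels, minimizing total
#' centroid distance among pairs closer than `max_dist_px` (optimal assignment
#' on the thresholded distance matrix; maximum-cardinality first, then minimum
#' total distance). ROIs with no admissible partner are dropped — these are
#' single-image detections. Implemented as a maximum-weight bipartite matching
#' with weight `C - d` for a constant `C` large enough that cardinality always
#' dominates distance.
#'
#' @param rois_445,rois_488 ROI tables from [extract_rois()] for the two
#'   channels of one field of view.
#' @param max_dist_px Hard centroid-distance gate in pixels.
#' @return A data frame of pairs ordered by `(roi_id_445, roi_id_488)` with
#'   columns `roi_id_445`, `roi_id_488`, `centroid_row`, `centroid_col` (445
#'   centroid), `centroid_distance_px`, `area_px_445`, `area_px_488`,
#'   `mean_intensity_445`, `mean_intensity_488`, `min_intensity_445`,
#'   `min_intensity_488`, `ratio`.
#' @export
pair_rois <- function(rois_445, rois_488, max_dist_px = 3) {
  stopifnot(is.data.frame(rois_445), is.data.frame(rois_488))
  if (max_dist_px <= 0) stop("max_dist_px must be > 0")
  empty <- data.frame(
    roi_id_445 = integer(), roi_id_488 = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    centroid_distance_px = numeric(),
    area_px_445 = integer(), area_px_488 = integer(),
    mean_intensity_445 = numeric(), mean_intensity_488 = numeric(),
    min_intensity_445 = numeric(), min_intensity_488 = numeric(),
    ratio = numeric()
  )
  n <- nrow(rois_445); m <- nrow(rois_488)
  if (n == 0 || m == 0) return(empty)
  d <- sqrt(
    outer(rois_445$centroid_row, rois_488$centroid_row, "-")^2 +
    outer(rois_445$centroid_col, rois_488$centroid_col, "-")^2
  )
  adm <- which(d <= max_dist_px, arr.ind = TRUE)
  if (nrow(adm) == 0) return(empty)

  big <- max_dist_px * min(n, m) + 1
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, n), rep(TRUE, m)),
    edges = as.vector(rbind(adm[, 1], n + adm[, 2]))
  )
  w <- big - d[adm]
  match <- igraph::max_bipartite_match(g, weights = w)$matching
  i <- which(!is.na(match[seq_len(n)]))
  if (length(i) == 0) return(empty)
  j <- match[i] - n
  out <- data.frame(
    roi_id_445 = rois_445$roi_id[i],
    roi_id_488 = rois_488$roi_id[j],
    centroid_row = rois_445$centroid_row[i],
    centroid_col = rois_445$centroid_col[i],
    centroid_distance_px = d[cbind(i, j)],
    area_px_445 = rois_445$area_px[i],
    area_px_488 = rois_488$area_px[j],
    mean_intensity_445 = rois_445$mean_intensity[i],
    mean_intensity_488 = rois_488$mean_intensity[j],
    min_intensity_445 = rois_445$min_intensity[i],
    min_intensity_488 = rois_488$min_intensity[j],
    ratio = NA_real_
  )
  out <- out[order(out$roi_id_445, out$roi_id_488), , drop = FALSE]
  rownames(out) <- NULL
  out$ratio <- pair_ratio(out)
  out
}

#' Discard pairs containing low-intensity pixels
#'
#' Keeps pairs whose minimum background-subtracted pixel intensity is at least
#' `min_pixel_intensity` in both channels; order is preserved.
#'
#' @param pairs Pair table from [pair_rois()].
#' @param min_pixel_intensity Intensity floor in counts (>= 0).
#' @return The filtered pair table.
#' @export
filter_pairs <- function(pairs, min_pixel_intensity = 5) {
  stopifnot(is.data.frame(pairs))
  if (min_pixel_intensity < 0) stop("min_pixel_intensity must be >= 0")
  if (nrow(pairs) == 0) return(pairs)
  keep <- pairs$min_intensity_445 >= min_pixel_intensity &
    pairs$min_intensity_488 >= min_pixel_intensity
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 488/445 intensity ratio of paired ROIs
#'
#' Ratio of the mean background-subtracted 488 intensity (over the 488 ROI's
#' pixels) to the mean background-subtracted 445 intensity (over the 445 ROI's
#' pixels). Ratio of ROI means, not mean of pixelwise ratios, for robustness to
#' sub-pixel registration error.
#'
#' @param pair One or more rows of a pair table (needs `mean_intensity_445`
#'   and `mean_intensity_488`).
#' @return Numeric vector of ratios.
#' @export
pair_ratio <- function(pair) {
  stopifnot(all(c("mean_intensity_445", "mean_intensity_488") %in% names(pair)))
  den <- pair$mean_intensity_445
  if (any(!is.finite(den)) || any(den <= 0)) {
    stop("degenerate ROI: mean 445 intensity must be positive")
  }
  pair$mean_intensity_488 / den
}
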