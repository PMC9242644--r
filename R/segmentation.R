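#' Local background subtraction (grayscale opening / rolling-ball analog)
#'
#' Estimates the local background as the grayscale morphological opening of the
#' image with a disk structuring element and returns the top-hat residual,
#' floored at 0. The envelope is estimated on a lightly Gaussian-smoothed copy
#' of the image (`smooth_sigma`): an opening of the raw image tracks the lower
#' envelope of the shot noise and leaves a positive residual offset under every
#' object, which would bias intensity ratios; smoothing the estimate removes
#' that offset while leaving the subtracted signal itself untouched. The disk
#' radius must exceed the radius of the largest object to be preserved, as with
#' any rolling-ball background. Opening commutes with positive scaling, so the
#' image is rescaled to \[0, 1\] internally for the morphology and rescaled
#' back.
#'
#' @param image Numeric intensity matrix.
#' @param radius_px Disk radius in pixels (>= 1, and at most half the smaller
#'   image dimension).
#' @param smooth_sigma Gaussian sigma (pixels) used when estimating the
#'   background envelope; 0 disables smoothing.
#' @return Background-subtracted matrix of the same shape, all values >= 0.
#' @export
subtract_background <- function(image, radius_px = 20, smooth_sigma = 1.5) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.finite(radius_px) || radius_px < 1) stop("radius_px must be >= 1")
  if (radius_px > min(dim(image)) / 2) {
    stop("radius_px (", radius_px, ") exceeds half the smaller image dimension")
  }
  m <- max(image)
  if (m <= 0) return(matrix(0, nrow(image), ncol(image)))
  base <- if (smooth_sigma > 0) EBImage::gblur(image / m, smooth_sigma) else
    image / m
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  bg <- EBImage::opening(base, brush) * m
  out <- image - matrix(as.numeric(bg), nrow(image), ncol(image))
  out[out < 0] <- 0
  out
}

#' Otsu threshold (between-class variance maximization)
#'
#' Builds an `n_bins` histogram over \[min, max\] of the image and returns the
#' bin edge maximizing the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2}, where class 0 is all pixels at or below the
#' candidate edge. Class means use the exact per-bin intensity sums, so for
#' integer images with at most `n_bins` distinct values the result coincides
#' with exhaustive maximization over all splits. Ties are broken toward the
#' lowest threshold. Foreground is defined as pixels strictly greater than the
#' returned threshold.
#'
#' @param image Numeric matrix (or vector) with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  if (any(!is.finite(v))) stop("image contains non-finite values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("no threshold exists: image is constant")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(v, bin)
  sums[as.integer(rownames(agg))] <- agg

  # pixels exactly on a candidate (left) bin edge belong to class 0 there
  cand <- edges[seq_len(n_bins)]
  on_edge <- v == cand[bin]
  eq_cnt <- numeric(n_bins); eq_sum <- numeric(n_bins)
  if (any(on_edge)) {
    be <- bin[on_edge]
    eq_cnt[seq_len(n_bins)] <- tabulate(be, nbins = n_bins)
    agg2 <- rowsum(v[on_edge], be)
    eq_sum[as.integer(rownames(agg2))] <- agg2
  }

  n_tot <- length(v); s_tot <- sum(v)
  c_below <- c(0, cumsum(cnt)[-n_bins])   # counts in bins 1..k-1
  s_below <- c(0, cumsum(sums)[-n_bins])
  n0 <- c_below + eq_cnt
  s0 <- s_below + eq_sum
  n1 <- n_tot - n0
  s1 <- s_tot - s0
  valid <- n0 > 0 & n1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (n0[valid] / n_tot) * (n1[valid] / n_tot) *
    (s0[valid] / n0[valid] - s1[valid] / n1[valid])^2
  cand[which.max(bcv)]
}

# connected-component labeling of a logical mask via the pixel adjacency graph
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list(idx = integer(), membership = integer()))
  lut <- integer(nr * nc)
  lut[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    r_rng <- seq_len(nr - dr)
    c_rng <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- mask[r_rng, c_rng, drop = FALSE]
    b <- mask[r_rng + dr, c_rng + dc, drop = FALSE]
    hit <- which(a & b)
    if (length(hit)) {
      # translate block-local indices back to full-image linear indices
      hr <- (hit - 1L) %% length(r_rng) + 1L
      hc <- (hit - 1L) %/% length(r_rng) + 1L
      p <- (c_rng[hc] - 1L) * nr + r_rng[hr]
      q <- (c_rng[hc] + dc - 1L) * nr + r_rng[hr] + dr
      edges <- c(edges, rbind(lut[p], lut[q]))
    }
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  list(idx = idx, membership = memb)
}

#' Extract ROIs (connected components above threshold)
#'
#' Labels connected components of `image > threshold` under the chosen
#' connectivity, discards components smaller than `min_area`, and reports each
#' surviving component with its unweighted centroid, area and mean/min
#' background-subtracted intensity. ROIs are pairwise disjoint and ordered
#' deterministically by their top-left pixel in row-major order.
#'
#' @param image Background-subtracted intensity matrix.
#' @param threshold Foreground threshold (strictly greater-than), typically
#'   from [otsu_threshold()].
#' @param min_area Minimum component area in pixels.
#' @param connectivity Pixel adjacency, 4 or 8.
#' @param channel Optional channel tag (445 or 488) carried into the output.
#' @return A data frame with one row per ROI: `roi_id`, `channel`, `area_px`,
#'   `centroid_row`, `centroid_col`, `mean_intensity`, `min_intensity`, and a
#'   list column `pixels` of linear pixel indices into `image`.
#' @export
extract_rois <- function(image, threshold, min_area = 4, connectivity = 8,
                         channel = NA_integer_) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  empty <- data.frame(
    roi_id = integer(), channel = integer(), area_px = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    mean_intensity = numeric(), min_intensity = numeric()
  )
  empty$pixels <- list()
  mask <- image > threshold
  lab <- label_components(mask, connectivity)
  if (length(lab$idx) == 0) return(empty)
  nr <- nrow(image)
  px_by_comp <- split(lab$idx, lab$membership)
  areas <- lengths(px_by_comp)
  keep <- areas >= min_area
  if (!any(keep)) return(empty)
  px_by_comp <- px_by_comp[keep]
  nc_img <- ncol(image)
  stats_tab <- lapply(px_by_comp, function(px) {
    rows <- (px - 1L) %% nr + 1L
    cols <- (px - 1L) %/% nr + 1L
    c(area = length(px),
      key = min((rows - 1) * nc_img + (cols - 1)),  # row-major top-left order
      crow = mean(rows), ccol = mean(cols),
      m = mean(image[px]), mn = min(image[px]))
  })
  st <- do.call(rbind, stats_tab)
  ord <- order(st[, "key"])
  out <- data.frame(
    roi_id = seq_along(ord),
    channel = channel,
    area_px = as.integer(st[ord, "area"]),
    centroid_row = st[ord, "crow"],
    centroid_col = st[ord, "ccol"],
    mean_intensity = st[ord, "m"],
    min_intensity = st[ord, "mn"]
  )
  out$pixels <- px_by_comp[ord]
  out
}

#' Segment one channel: background subtraction, Otsu, component extraction
#'
#' Convenience wrapper chaining [subtract_background()], [otsu_threshold()] and
#' [extract_rois()] with one parameter set.
#'
#' @param image Raw intensity matrix.
#' @param params List with `background_radius_px`, `n_bins`, `min_area_px`,
#'   `connectivity` (see [segmentation_params()]).
#' @param channel Channel tag for the output.
#' @return ROI table as from [extract_rois()].
#' @export
segment_channel <- function(image, params = segmentation_params(),
                            channel = NA_integer_) {
  bs <- subtract_background(image, params$background_radius_px,
                            params$background_smooth_sigma)
  thr <- tryCatch(otsu_threshold(bs, params$n_bins), error = function(e) NA)
  if (is.na(thr)) {
    return(extract_rois(bs, Inf, params$min_area_px, params$connectivity,
                        channel))
  }
  extract_rois(bs, thr, params$min_area_px, params$connectivity, channel)
}

#' Segmentation parameter set
#'
#' @param background_radius_px Disk radius of the local background opening.
#' @param background_smooth_sigma Gaussian sigma of the background-envelope
#'   smoothing (see [subtract_background()]).
#' @param n_bins Otsu histogram bins.
#' @param min_area_px Minimum ROI area.
#' @param connectivity 4 or 8.
#' @export
segmentation_params <- function(background_radius_px = 20,
                                background_smooth_sigma = 1.5,
                                n_bins = 256,
                                min_area_px = 4, connectivity = 8) {
  list(background_radius_px = background_radius_px,
       background_smooth_sigma = background_smooth_sigma, n_bins = n_bins,
       min_area_px = min_area_px, connectivity = connectivity)
}

#' Write an ROI table to CSV
#'
#' Emits `rois_{channel}.csv` without the pixel list column.
#' @param rois ROI table from [extract_rois()].
#' @param dir Output directory.
#' @param channel Channel tag used in the file name.
#' @export
write_rois <- function(rois, dir, channel) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, sprintf("rois_%s.csv", channel))
  utils::write.csv(
    rois[, c("roi_id", "channel", "centroid_row", "centroid_col", "area_px",
             "mean_intensity", "min_intensity")],
    path, row.names = FALSE
  )
  invisible(path)
}
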