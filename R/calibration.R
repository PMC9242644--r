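#' Assemble calibration points from per-cell paired ROIs
#'
#' Each calibration point is the mean 488/445 ratio over one cell's paired
#' lysosomes at one clamped buffer pH, matching how a standard curve is built:
#' ionophores equilibrate lysosomal pH to the buffer, and each cell contributes
#' one averaged symbol.
#'
#' @param buffer_ph Vector of buffer pH values, one per cell.
#' @param cell_pairs List (same length) of paired-ROI tables as returned by
#'   [pair_rois()] / [filter_pairs()]; each must have a `ratio` column.
#' @return A data frame with columns `buffer_ph`, `cell_mean_ratio`,
#'   `n_lysosomes`.
#' @export
calibration_points <- function(buffer_ph, cell_pairs) {
  stopifnot(length(buffer_ph) == length(cell_pairs))
  ok <- vapply(cell_pairs, function(p) is.data.frame(p) && nrow(p) > 0, logical(1))
  if (!all(ok)) {
    stop("every calibration cell must contribute at least one paired ROI")
  }
  data.frame(
    buffer_ph = as.numeric(buffer_ph),
    cell_mean_ratio = vapply(cell_pairs, function(p) mean(p$ratio), numeric(1)),
    n_lysosomes = vapply(cell_pairs, nrow, integer(1))
  )
}

#' Fit a four-parameter logistic calibration curve
#'
#' Least-squares fit of the ratio-pH sigmoid (see [ratio_ph_law()]) to per-cell
#' mean ratios measured across clamped-pH buffers. Initialization: `r_min` and
#' `r_max` from the observed ratio extremes, `ph50` from linear interpolation of
#' the per-buffer mean ratios at the ratio midpoint, `slope_h = 1`. Parameters
#' are bounded (`r_min >= 0`, `slope_h` in \[0.1, 5\]) and the optimizer runs to
#' a residual-sum-of-squares tolerance of 1e-10.
#'
#' @param points Data frame with columns `buffer_ph` and `cell_mean_ratio`
#'   (see [calibration_points()]). At least 4 distinct buffer pH values and 8
#'   points overall are required.
#' @return A `calibration_curve` object (also a `ratio_ph_law`) with elements
#'   `r_min`, `r_max`, `ph50`, `slope_h`, `valid_range` (span of buffer pHs),
#'   `fit_rss` and `n_points`.
#' @export
fit_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("buffer_ph", "cell_mean_ratio") %in% names(points)))
  ph <- points$buffer_ph
  r <- points$cell_mean_ratio
  if (any(!is.finite(ph)) || any(!is.finite(r)) || any(r <= 0)) {
    stop("calibration points must have finite buffer_ph and positive ratios")
  }
  if (length(unique(ph)) < 4) {
    stop("calibration requires >= 4 distinct buffer pH values, got ",
         length(unique(ph)))
  }
  if (length(ph) < 8) {
    stop("calibration requires >= 8 points overall, got ", length(ph))
  }

  r_min0 <- min(r)
  r_max0 <- max(r)
  by_ph <- tapply(r, ph, mean)
  phs <- as.numeric(names(by_ph))
  mid <- (r_min0 + r_max0) / 2
  ord <- order(by_ph)
  ph50_0 <- tryCatch(
    stats::approx(as.numeric(by_ph)[ord], phs[ord], xout = mid, ties = mean)$y,
    error = function(e) NA_real_
  )
  if (!is.finite(ph50_0)) ph50_0 <- stats::median(ph)

  dat <- data.frame(ph = ph, r = r)
  do_fit <- function(ctrl) tryCatch(
    minpack.lm::nlsLM(
      r ~ r_min + (r_max - r_min) / (1 + 10^(slope_h * (ph50 - ph))),
      data = dat,
      start = list(r_min = r_min0, r_max = r_max0, ph50 = ph50_0, slope_h = 1),
      lower = c(r_min = 0, r_max = 0, ph50 = min(ph) - 5, slope_h = 0.1),
      upper = c(r_min = Inf, r_max = Inf, ph50 = max(ph) + 5, slope_h = 5),
      control = ctrl
    ),
    error = function(e) e
  )
  fit <- do_fit(minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500))
  if (inherits(fit, "error")) {
    fit <- do_fit(minpack.lm::nls.lm.control(maxiter = 500))
  }
  if (inherits(fit, "error")) {
    stop("calibration fit failed to converge: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  if (cf[["r_max"]] <= cf[["r_min"]] || cf[["slope_h"]] <= 0) {
    stop(sprintf(
      "fitted calibration curve is non-monotonic (r_min=%.4g, r_max=%.4g, slope_h=%.4g)",
      cf[["r_min"]], cf[["r_max"]], cf[["slope_h"]]
    ))
  }
  structure(
    list(
      r_min = unname(cf[["r_min"]]),
      r_max = unname(cf[["r_max"]]),
      ph50 = unname(cf[["ph50"]]),
      slope_h = unname(cf[["slope_h"]]),
      valid_range = range(ph),
      fit_rss = sum(stats::resid(fit)^2),
      n_points = length(ph)
    ),
    class = c("calibration_curve", "ratio_ph_law")
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_curve> r_min=%.4g r_max=%.4g ph50=%.4g slope_h=%.4g\n",
           "  valid pH range [%.2f, %.2f], RSS=%.3g over %d points\n"),
    x$r_min, x$r_max, x$ph50, x$slope_h,
    x$valid_range[1], x$valid_range[2], x$fit_rss, x$n_points
  ))
  invisible(x)
}

#' Write a fitted calibration curve and its points to disk
#'
#' Emits `calibration.json` (parameters, validity range, RSS, point count) and
#' `calibration_points.csv` alongside it.
#'
#' @param curve A `calibration_curve`.
#' @param points The data frame the curve was fitted to.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_calibration <- function(curve, points, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "calibration.json")
  csv_path <- file.path(dir, "calibration_points.csv")
  jsonlite::write_json(
    list(
      r_min = curve$r_min, r_max = curve$r_max, ph50 = curve$ph50,
      slope_h = curve$slope_h, valid_range = curve$valid_range,
      fit_rss = curve$fit_rss, n_points = curve$n_points
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(points, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
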