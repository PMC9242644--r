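#' Four-parameter logistic ratio-pH law
#'
#' The dual-excitation ratio of a ratiometric pH dye follows a sigmoid in pH:
#' \deqn{R(pH) = r_{min} + \frac{r_{max} - r_{min}}{1 + 10^{h\,(pH_{50} - pH)}}}
#' with floor `r_min`, ceiling `r_max`, midpoint `ph50` (the apparent pKa) and
#' base-10 slope `slope_h`. The curve is strictly increasing in pH whenever
#' `r_max > r_min` and `slope_h > 0`. The same parameterization serves both as
#' the ground-truth law of the synthetic image generator and as the fitted
#' calibration curve (see [fit_calibration()]).
#'
#' @param r_min Dimensionless ratio floor (low-pH asymptote), must be > 0.
#' @param r_max Dimensionless ratio ceiling (high-pH asymptote), must exceed
#'   `r_min`.
#' @param ph50 Midpoint in pH units; for Oregon Green 488 the apparent pKa is
#'   about 4.8.
#' @param slope_h Dimensionless base-10 slope, must be > 0.
#' @return An object of class `ratio_ph_law`.
#' @examples
#' law <- ratio_ph_law(0.2, 2.0, 4.8, 1.0)
#' ratio_from_ph(law, 4.8)  # midpoint: (0.2 + 2.0) / 2
#' @export
ratio_ph_law <- function(r_min, r_max, ph50, slope_h) {
  vals <- c(r_min = r_min, r_max = r_max, ph50 = ph50, slope_h = slope_h)
  if (!all(is.finite(vals))) {
    stop("ratio_ph_law parameters must be finite numbers")
  }
  if (r_min <= 0 || r_max <= r_min) {
    stop("ratio_ph_law requires r_max > r_min > 0")
  }
  if (slope_h <= 0) {
    stop("ratio_ph_law requires slope_h > 0")
  }
  structure(
    list(r_min = r_min, r_max = r_max, ph50 = ph50, slope_h = slope_h),
    class = "ratio_ph_law"
  )
}

#' @export
print.ratio_ph_law <- function(x, ...) {
  cat(sprintf(
    "<ratio_ph_law> r_min=%.4g  r_max=%.4g  ph50=%.4g  slope_h=%.4g\n",
    x$r_min, x$r_max, x$ph50, x$slope_h
  ))
  invisible(x)
}

#' Evaluate a ratio-pH law
#'
#' @param curve A [ratio_ph_law()] or [fit_calibration()] result.
#' @param ph Vector of pH values.
#' @return Predicted 488/445 ratios.
#' @export
ratio_from_ph <- function(curve, ph) {
  stopifnot(inherits(curve, "ratio_ph_law"), is.numeric(ph))
  curve$r_min +
    (curve$r_max - curve$r_min) / (1 + 10^(curve$slope_h * (curve$ph50 - ph)))
}

#' Invert a calibration curve: ratio to pH
#'
#' Analytic inverse of the four-parameter logistic,
#' \eqn{pH = pH_{50} - \frac{1}{h} \log_{10}\!\big(\frac{r_{max}-r_{min}}
#' {R - r_{min}} - 1\big)}. Ratios at or outside the open interval
#' `(r_min, r_max)` cannot be inverted (the dye is saturated there); they are
#' clamped to the ends of the curve's validity range and flagged. Finite
#' inversions that land outside the validity range (the span of calibration
#' buffer pHs) are likewise clamped and flagged.
#'
#' @param curve A `calibration_curve` (or a `ratio_ph_law` carrying a
#'   `valid_range` element).
#' @param ratio Vector of measured 488/445 ratios; must be finite.
#' @return Numeric vector of pH values with a logical attribute `"clamped"`
#'   marking entries that were clamped.
#' @seealso [ratio_from_ph()] for the forward direction.
#' @export
ph_from_ratio <- function(curve, ratio) {
  stopifnot(inherits(curve, "ratio_ph_law"))
  if (!is.numeric(ratio) || any(!is.finite(ratio))) {
    stop("ratio must be finite; got non-finite value(s)")
  }
  vr <- curve$valid_range
  if (is.null(vr) || length(vr) != 2 || !all(is.finite(vr)) || vr[1] >= vr[2]) {
    stop("curve carries no usable valid_range; fit a calibration curve first")
  }
  ph <- numeric(length(ratio))
  clamped <- logical(length(ratio))
  lo <- ratio <= curve$r_min
  hi <- ratio >= curve$r_max
  mid <- !lo & !hi
  ph[lo] <- vr[1]
  ph[hi] <- vr[2]
  clamped[lo | hi] <- TRUE
  if (any(mid)) {
    span <- curve$r_max - curve$r_min
    ph[mid] <- curve$ph50 -
      (1 / curve$slope_h) * log10(span / (ratio[mid] - curve$r_min) - 1)
  }
  out <- ph < vr[1] | ph > vr[2]
  ph <- pmin(pmax(ph, vr[1]), vr[2])
  attr(ph, "clamped") <- clamped | out
  ph
}
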