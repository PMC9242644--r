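#' Convert paired ROIs to per-lysosome pH and size records
#'
#' Applies the calibration inverse to each surviving pair's ratio and converts
#' the 445-channel ROI area to square micrometres. Clamped inversions (ratios
#' outside the calibration's dynamic range, or pH outside the buffer span) are
#' flagged, not dropped.
#'
#' @param pairs Pair table from [filter_pairs()]; must carry a `cell_id`
#'   column, or supply one via `cell_id`.
#' @param curve A `calibration_curve`.
#' @param pixel_size_um Physical pixel size; area is
#'   `area_px_445 * pixel_size_um^2`.
#' @param experiment_id,condition Labels carried into the records.
#' @param cell_id Optional single cell id if `pairs` lacks the column.
#' @return A data frame: `experiment_id`, `condition`, `cell_id`,
#'   `lysosome_id`, `ratio`, `ph`, `area_um2`, `clamped`.
#' @export
measure_lysosomes <- function(pairs, curve, pixel_size_um,
                              experiment_id = "exp1", condition = "control",
                              cell_id = NULL) {
  stopifnot(is.data.frame(pairs), inherits(curve, "ratio_ph_law"))
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (!"cell_id" %in% names(pairs)) {
    if (is.null(cell_id)) stop("pairs must carry cell_id (or pass cell_id=)")
    pairs$cell_id <- cell_id
  }
  if (nrow(pairs) == 0) {
    return(data.frame(experiment_id = character(), condition = character(),
                      cell_id = integer(), lysosome_id = integer(),
                      ratio = numeric(), ph = numeric(), area_um2 = numeric(),
                      clamped = logical()))
  }
  ph <- ph_from_ratio(curve, pairs$ratio)
  data.frame(
    experiment_id = experiment_id,
    condition = condition,
    cell_id = pairs$cell_id,
    lysosome_id = seq_len(nrow(pairs)),
    ratio = pairs$ratio,
    ph = as.numeric(ph),
    area_um2 = pairs$area_px_445 * pixel_size_um^2,
    clamped = attr(ph, "clamped")
  )
}

#' Aggregate lysosome measurements to cell and condition summaries
#'
#' Cell mean = unweighted mean over the cell's lysosomes; condition mean and
#' SEM are computed over cell means, so cells are weighted equally regardless
#' of how many lysosomes they contain (the convention behind per-cell symbols
#' in ratiometric imaging figures). Cells with fewer than
#' `min_lysosomes_per_cell` records are excluded and reported.
#'
#' @param measurements Records from [measure_lysosomes()] (one condition).
#' @param min_lysosomes_per_cell Minimum records per qualifying cell.
#' @return A list: `cells` (cell_id, n_lysosomes, mean_ph, mean_area_um2),
#'   `condition` (condition, n_cells, mean_ph, sem_ph, mean_area_um2,
#'   sem_area_um2, n_lysosomes, clamped_fraction), `dropped_cells`.
#' @export
summarize_measurements <- function(measurements, min_lysosomes_per_cell = 5) {
  stopifnot(is.data.frame(measurements))
  if (nrow(measurements) == 0) stop("no measurements to summarize")
  if (length(unique(measurements$condition)) > 1) {
    stop("summarize_measurements expects a single condition; split first")
  }
  by_cell <- split(measurements, measurements$cell_id)
  cells <- data.frame(
    cell_id = as.integer(names(by_cell)),
    n_lysosomes = vapply(by_cell, nrow, integer(1)),
    mean_ph = vapply(by_cell, function(d) mean(d$ph), numeric(1)),
    mean_area_um2 = vapply(by_cell, function(d) mean(d$area_um2), numeric(1))
  )
  rownames(cells) <- NULL
  qualifying <- cells$n_lysosomes >= min_lysosomes_per_cell
  dropped <- cells$cell_id[!qualifying]
  cells <- cells[qualifying, , drop = FALSE]
  if (nrow(cells) == 0) {
    stop("no cell has >= ", min_lysosomes_per_cell, " lysosomes")
  }
  n_cells <- nrow(cells)
  sem <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  condition <- data.frame(
    condition = measurements$condition[1],
    n_cells = n_cells,
    mean_ph = mean(cells$mean_ph),
    sem_ph = sem(cells$mean_ph),
    mean_area_um2 = mean(cells$mean_area_um2),
    sem_area_um2 = sem(cells$mean_area_um2),
    n_lysosomes = sum(cells$n_lysosomes),
    clamped_fraction = mean(measurements$clamped)
  )
  list(cells = cells, condition = condition, dropped_cells = dropped)
}

#' Proton concentration fold change from a pH shift
#'
#' `10^(-delta_ph)`: a pH decrease of 0.31 units corresponds to a ~2.04-fold
#' increase in free proton concentration.
#'
#' @param delta_ph pH shift (treated minus control).
#' @return The fold change in \[H+\].
#' @export
proton_fold_change <- function(delta_ph) {
  stopifnot(is.numeric(delta_ph), all(is.finite(delta_ph)))
  10^(-delta_ph)
}

#' Condition shift: delta pH, proton fold change, delta size
#'
#' Sign convention: treated minus control, so an acidifying treatment gives a
#' negative `delta_ph` and a `proton_fold` above 1.
#'
#' @param control,treated Condition summary rows from
#'   [summarize_measurements()].
#' @return A one-row data frame: `delta_ph`, `proton_fold`, `delta_area_um2`.
#' @export
ph_shift <- function(control, treated) {
  stopifnot(is.data.frame(control), is.data.frame(treated),
            nrow(control) == 1, nrow(treated) == 1)
  delta_ph <- treated$mean_ph - control$mean_ph
  data.frame(
    control = control$condition,
    treated = treated$condition,
    delta_ph = delta_ph,
    proton_fold = proton_fold_change(delta_ph),
    delta_area_um2 = treated$mean_area_um2 - control$mean_area_um2
  )
}

#' Empirical cumulative distribution of lysosomal pH
#'
#' Fraction of values at or below each sorted unique value; non-decreasing and
#' ending exactly at 1.
#'
#' @param values Numeric vector (>= 1 finite value).
#' @return Data frame with columns `ph` and `fraction`.
#' @export
ph_ecdf <- function(values) {
  if (length(values) == 0) stop("ecdf of an empty vector is undefined")
  if (any(!is.finite(values))) stop("values must be finite")
  x <- sort(unique(values))
  data.frame(ph = x, fraction = stats::ecdf(values)(x))
}

#' Pearson correlation between lysosomal pH and size
#'
#' Per-lysosome correlation with a two-sided t-distribution p-value; used to
#' ask whether acidification tracks swelling at the single-organelle level.
#'
#' @param measurements Records with `ph` and `area_um2` columns (>= 3 rows).
#' @return List with `r`, `p_value`, `n`.
#' @export
ph_size_correlation <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("ph", "area_um2") %in% names(measurements)))
  if (nrow(measurements) < 3) stop("need >= 3 records")
  if (stats::sd(measurements$ph) == 0 || stats::sd(measurements$area_um2) == 0) {
    stop("zero variance in ph or area_um2")
  }
  ct <- stats::cor.test(measurements$ph, measurements$area_um2,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(measurements))
}

#' Two-sample t-test (classic Student's, pooled variance)
#'
#' Unpaired: pooled-variance Student's t. Paired: t-test on the paired
#' differences. Two-sided p-values. Welch's correction available by flag for
#' the unpaired case.
#'
#' @param a,b Numeric samples; for `paired = TRUE`, equal lengths.
#' @param paired Paired test on `a - b`?
#' @param var_equal Pool variances (classic Student's)? Ignored when paired.
#' @return List with `t`, `p_value`, `df`.
#' @export
two_sample_test <- function(a, b, paired = FALSE, var_equal = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal lengths")
    if (length(a) < 2) stop("paired test requires >= 2 pairs")
    if (stats::sd(a - b) == 0) stop("degenerate variance: differences are constant")
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      stop("degenerate variance: both samples are constant")
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}
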