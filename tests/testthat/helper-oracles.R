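# Independent oracles and small fixture builders used across the suite.

# Wrap a ground-truth ratio law as an invertible curve with a validity range,
# bypassing the fitting path.
exact_curve <- function(law = ratio_ph_law(0.2, 2.0, 4.8, 1.0),
                        valid_range = c(3, 7)) {
  structure(c(unclass(law), list(valid_range = valid_range)),
            class = c("calibration_curve", "ratio_ph_law"))
}

# Exhaustive Otsu oracle for integer-valued images: tries every split
# "background <= T" for T in min..max-1, maximizes w0*w1*(mu0-mu1)^2, breaks
# ties toward the lowest T. Returns the foreground mask.
brute_force_otsu_mask <- function(v) {
  vals <- sort(unique(v))
  cand <- vals[-length(vals)]
  best_bcv <- -Inf
  best_T <- NA
  n <- length(v)
  for (T in cand) {
    in0 <- v <= T
    n0 <- sum(in0); n1 <- n - n0
    bcv <- (n0 / n) * (n1 / n) * (mean(v[in0]) - mean(v[!in0]))^2
    if (bcv > best_bcv + 1e-12) { best_bcv <- bcv; best_T <- T }
  }
  v > best_T
}

# Exact maximum-cardinality, minimum-total-distance matching by bitmask
# dynamic programming over the second ROI set (feasible for <= 8 ROIs).
# Returns c(count, total_distance).
brute_force_match <- function(d, max_dist) {
  n <- nrow(d); m <- ncol(d)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, mask) {
    if (i > n) return(c(0, 0))
    key <- paste0(i, "_", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, mask)
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L && d[i, j] <= max_dist) {
        cand <- rec(i + 1L, bitwOr(mask, bit)) + c(1, d[i, j])
        if (cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] < best[2] - 1e-9)) {
          best <- cand
        }
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 0L)
}

# Minimal ROI table for pairing tests (centroids only).
roi_table <- function(rows, cols, mean_intensity = 100, min_intensity = 50) {
  n <- length(rows)
  out <- data.frame(
    roi_id = seq_len(n), channel = rep_len(NA_integer_, n),
    area_px = rep_len(9L, n),
    centroid_row = rows, centroid_col = cols,
    mean_intensity = rep_len(mean_intensity, n),
    min_intensity = rep_len(min_intensity, n)
  )
  out$pixels <- replicate(n, integer(0), simplify = FALSE)
  out
}

# Small single-cell scene used by several segmentation/pairing tests.
tiny_scene <- function(n_lysosomes = 6, ph_mean = 4.5, ph_sd = 0, seed = 1,
                       shape = c(96L, 96L)) {
  make_scene(scene_config(
    n_cells = 1, lysosomes_per_cell = n_lysosomes, image_shape = shape,
    ph_mean = ph_mean, ph_sd = ph_sd, seed = seed
  ))
}
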