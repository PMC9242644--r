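#' Scene configuration for the synthetic imaging generator
#'
#' Describes one synthetic field of view: elliptical, non-overlapping cells
#' containing punctate lysosomes rendered as isotropic Gaussian spots. Each
#' lysosome carries a true pH drawn from a Normal distribution truncated to
#' \[3.0, 7.5\] (the span of the calibration buffers plus margin) and a dye
#' amount drawn log-normally; the ground-truth ratio law links true pH to the
#' expected 488/445 intensity ratio.
#'
#' @param n_cells Number of cells in the field.
#' @param lysosomes_per_cell Exact number of lysosomes placed in each cell.
#' @param image_shape Integer `(rows, cols)` of the field in pixels.
#' @param pixel_size_um Physical pixel size in micrometres (no instrument
#'   default exists; 0.16 um/px is a typical 60x camera value).
#' @param radius_mean,radius_sd Mean and SD (pixels) of the Gaussian spot sigma;
#'   the spot is truncated at 3 sigma.
#' @param ph_mean,ph_sd Mean and SD of the true lysosomal pH (truncated Normal).
#' @param dye_meanlog,dye_sdlog Log-normal parameters of the per-lysosome dye
#'   amount (relative units; peak photon count is `photon_scale * dye_amount`).
#' @param law Ground-truth [ratio_ph_law()].
#' @param condition Condition label carried into all outputs.
#' @param seed Integer seed; scene construction is deterministic given it.
#' @param min_separation_factor Dart-throwing placement keeps lysosome centers
#'   at least `factor * (sigma_i + sigma_j)` apart (relaxed gradually if the
#'   field is too crowded to satisfy it).
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_cells = 2,
                         lysosomes_per_cell = 30,
                         image_shape = c(256L, 256L),
                         pixel_size_um = 0.16,
                         radius_mean = 1.6,
                         radius_sd = 0.25,
                         ph_mean = 4.32,
                         ph_sd = 0.15,
                         dye_meanlog = 0,
                         dye_sdlog = 0.3,
                         law = ratio_ph_law(0.2, 2.0, 4.8, 1.0),
                         condition = "control",
                         seed = 1L,
                         min_separation_factor = 3) {
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    stop("image_shape must be two positive pixel dimensions (>= 8)")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (radius_mean <= 0 || radius_sd < 0) {
    stop("radius parameters must be positive (mean) and non-negative (sd)")
  }
  if (n_cells < 0 || lysosomes_per_cell < 0) {
    stop("counts must be non-negative")
  }
  if (ph_sd < 0 || dye_sdlog < 0) stop("dispersion parameters must be >= 0")
  stopifnot(inherits(law, "ratio_ph_law"))
  structure(
    list(
      n_cells = as.integer(n_cells),
      lysosomes_per_cell = as.integer(lysosomes_per_cell),
      image_shape = as.integer(image_shape),
      pixel_size_um = pixel_size_um,
      radius_mean = radius_mean, radius_sd = radius_sd,
      ph_mean = ph_mean, ph_sd = ph_sd,
      dye_meanlog = dye_meanlog, dye_sdlog = dye_sdlog,
      law = law, condition = condition, seed = as.integer(seed),
      min_separation_factor = min_separation_factor
    ),
    class = "scene_config"
  )
}

# truncated-Normal draws via the inverse CDF (exact, vectorized)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# non-overlapping ellipse layout on a jittered grid; returns cells data frame
# and an integer label image (0 = background)
place_cells <- function(n_cells, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (n_cells == 0) {
    return(list(
      cells = data.frame(cell_id = integer(), center_row = numeric(),
                         center_col = numeric(), semi_row = numeric(),
                         semi_col = numeric()),
      label = matrix(0L, nr, nc)
    ))
  }
  g_rows <- floor(sqrt(n_cells))
  g_cols <- ceiling(n_cells / g_rows)
  tile_r <- nr / g_rows
  tile_c <- nc / g_cols
  cells <- data.frame(
    cell_id = seq_len(n_cells),
    center_row = numeric(n_cells), center_col = numeric(n_cells),
    semi_row = numeric(n_cells), semi_col = numeric(n_cells)
  )
  for (i in seq_len(n_cells)) {
    gr <- (i - 1) %/% g_cols
    gc <- (i - 1) %% g_cols
    jit <- stats::runif(2, -0.04, 0.04)
    cells$center_row[i] <- (gr + 0.5 + jit[1]) * tile_r
    cells$center_col[i] <- (gc + 0.5 + jit[2]) * tile_c
    cells$semi_row[i] <- tile_r * stats::runif(1, 0.36, 0.42)
    cells$semi_col[i] <- tile_c * stats::runif(1, 0.36, 0.42)
  }
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  label <- matrix(0L, nr, nc)
  for (i in seq_len(n_cells)) {
    inside <- ((rr - cells$center_row[i]) / cells$semi_row[i])^2 +
      ((cc - cells$center_col[i]) / cells$semi_col[i])^2 <= 1
    label[inside] <- i
  }
  list(cells = cells, label = label)
}

#' Build a synthetic scene (ground truth)
#'
#' Draws cell geometry, then per cell the lysosome radii, dye amounts and true
#' pH values, then places lysosome centers inside the cell ellipse by dart
#' throwing with a minimum-separation rule. Deterministic for a fixed
#' `cfg$seed`; every lysosome center lies inside its cell's mask and all true
#' pH values are within \[3.0, 7.5\].
#'
#' @param cfg A [scene_config()].
#' @return A list of class `synthetic_scene` with elements `image_shape`,
#'   `pixel_size_um`, `cells` (data frame), `cell_label` (integer matrix),
#'   `lysosomes` (data frame: `cell_id`, `lysosome_id`, `row`, `col`,
#'   `radius_px`, `dye_amount`, `true_ph`), `law`, `condition`, `seed`.
#' @export
make_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  shape <- cfg$image_shape
  layout <- place_cells(cfg$n_cells, shape)

  lys <- vector("list", cfg$n_cells)
  next_id <- 1L
  for (i in seq_len(cfg$n_cells)) {
    n <- cfg$lysosomes_per_cell
    if (n == 0) next
    sigma <- pmax(rtrunc_norm(n, cfg$radius_mean, cfg$radius_sd,
                              0.5, cfg$radius_mean + 4 * cfg$radius_sd), 0.5)
    dye <- stats::rlnorm(n, cfg$dye_meanlog, cfg$dye_sdlog)
    true_ph <- rtrunc_norm(n, cfg$ph_mean, cfg$ph_sd, 3.0, 7.5)
    pos <- place_lysosomes(
      n, sigma, layout$cells[i, ], shape, cfg$min_separation_factor
    )
    lys[[i]] <- data.frame(
      cell_id = i,
      lysosome_id = seq.int(next_id, next_id + n - 1L),
      row = pos$row, col = pos$col,
      radius_px = sigma, dye_amount = dye, true_ph = true_ph
    )
    next_id <- next_id + n
  }
  lysosomes <- if (length(lys)) do.call(rbind, lys) else
    data.frame(cell_id = integer(), lysosome_id = integer(), row = numeric(),
               col = numeric(), radius_px = numeric(), dye_amount = numeric(),
               true_ph = numeric())

  structure(
    list(
      image_shape = shape, pixel_size_um = cfg$pixel_size_um,
      cells = layout$cells, cell_label = layout$label,
      lysosomes = lysosomes, law = cfg$law,
      condition = cfg$condition, seed = cfg$seed
    ),
    class = "synthetic_scene"
  )
}

# dart-throwing placement inside one ellipse; separation relaxes by 10% steps
# if the field is too crowded, never below direct-contact spacing
place_lysosomes <- function(n, sigma, cell, shape, sep_factor) {
  rows <- numeric(n); cols <- numeric(n)
  margin_r <- pmin(cell$semi_row - 3 * sigma - 1, cell$semi_row * 0.95)
  margin_c <- pmin(cell$semi_col - 3 * sigma - 1, cell$semi_col * 0.95)
  if (any(margin_r <= 0) || any(margin_c <= 0)) {
    stop("lysosome radius too large for the cell; enlarge image_shape")
  }
  fac <- sep_factor
  for (i in seq_len(n)) {
    placed <- FALSE
    while (!placed) {
      for (try in seq_len(400)) {
        u <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1))
        r <- cell$center_row + rad * margin_r[i] * sin(u)
        c <- cell$center_col + rad * margin_c[i] * cos(u)
        r <- min(max(r, 3 * sigma[i] + 1), shape[1] - 3 * sigma[i] - 1)
        c <- min(max(c, 3 * sigma[i] + 1), shape[2] - 3 * sigma[i] - 1)
        if (i == 1) { ok <- TRUE } else {
          j <- seq_len(i - 1)
          d <- sqrt((rows[j] - r)^2 + (cols[j] - c)^2)
          ok <- all(d >= fac * (sigma[j] + sigma[i]))
        }
        if (ok) { rows[i] <- r; cols[i] <- c; placed <- TRUE; break }
      }
      if (!placed) {
        fac <- fac * 0.9
        if (fac < 1) stop("could not place lysosomes without overlap; ",
                          "reduce counts or radii, or enlarge the cell")
      }
    }
  }
  list(row = rows, col = cols)
}

#' Camera/illumination noise model
#'
#' Expected per-pixel counts are `photon_scale * dye_amount * G(x)` for the
#' 445 nm channel and the same scaled by the ratio law for 488 nm, plus a flat
#' background and a planar illumination gradient. Counts are Poisson-sampled
#' (shot noise), then Gaussian read noise is added and the result clipped at 0.
#'
#' @param background_level Flat background, counts per channel.
#' @param gradient_amplitude Peak-to-origin amplitude of a planar background
#'   gradient, counts.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param photon_scale Expected peak counts per unit dye amount.
#' @param shot_noise Set `FALSE` to skip Poisson sampling and render exact
#'   expected values (used with all-zero noise for ground-truth identities).
#' @param seed Integer seed used by [render_image_pair()].
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(background_level = 20,
                        gradient_amplitude = 10,
                        read_noise_sd = 2,
                        photon_scale = 300,
                        shot_noise = TRUE,
                        seed = 1L) {
  vals <- c(background_level, gradient_amplitude, read_noise_sd, photon_scale)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise model parameters must be finite and non-negative")
  }
  structure(
    list(background_level = background_level,
         gradient_amplitude = gradient_amplitude,
         read_noise_sd = read_noise_sd,
         photon_scale = photon_scale,
         shot_noise = isTRUE(shot_noise),
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Exact-expected-value noise model (no background, no noise)
#' @return A [noise_model()] with all noise sources off.
#' @export
noiseless_noise_model <- function(photon_scale = 300) {
  noise_model(background_level = 0, gradient_amplitude = 0, read_noise_sd = 0,
              photon_scale = photon_scale, shot_noise = FALSE)
}

#' Render the two-channel image pair of a scene
#'
#' Each lysosome contributes an isotropic Gaussian spot truncated at 3 sigma.
#' The 445 nm (reference) channel is pH-independent; the 488 nm channel is the
#' same profile scaled by the ground-truth ratio law at the lysosome's true pH,
#' so the expected per-spot intensity ratio equals `R(true_ph)` exactly.
#'
#' @param scene A [make_scene()] result.
#' @param noise A [noise_model()].
#' @return A list of class `image_pair`: matrices `ch445` and `ch488` (counts,
#'   same shape), `pixel_size_um`, `labels` (condition, seed).
#' @export
render_image_pair <- function(scene, noise) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(noise, "noise_model"))
  set.seed(noise$seed)
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  e445 <- matrix(0, nr, nc)
  e488 <- matrix(0, nr, nc)
  lys <- scene$lysosomes
  if (nrow(lys)) {
    ratios <- ratio_from_ph(scene$law, lys$true_ph)
    for (i in seq_len(nrow(lys))) {
      s <- lys$radius_px[i]
      ext <- ceiling(3 * s)
      r0 <- max(1L, floor(lys$row[i] - ext)); r1 <- min(nr, ceiling(lys$row[i] + ext))
      c0 <- max(1L, floor(lys$col[i] - ext)); c1 <- min(nc, ceiling(lys$col[i] + ext))
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - lys$row[i])^2, (cc - lys$col[i])^2, "+")
      g <- exp(-d2 / (2 * s^2))
      g[d2 > (3 * s)^2] <- 0
      amp <- noise$photon_scale * lys$dye_amount[i]
      e445[rr, cc] <- e445[rr, cc] + amp * g
      e488[rr, cc] <- e488[rr, cc] + amp * ratios[i] * g
    }
  }
  plane <- (outer(seq(0, 1, length.out = nr), seq(0, 1, length.out = nc), "+")) / 2
  bg <- noise$background_level + noise$gradient_amplitude * plane
  lam445 <- e445 + bg
  lam488 <- e488 + bg
  sample_channel <- function(lam) {
    x <- if (noise$shot_noise) {
      matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    } else lam
    if (noise$read_noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, noise$read_noise_sd),
                      nrow(x), ncol(x))
    }
    pmax(x, 0)
  }
  structure(
    list(ch445 = sample_channel(lam445), ch488 = sample_channel(lam488),
         pixel_size_um = scene$pixel_size_um,
         labels = list(condition = scene$condition, scene_seed = scene$seed,
                       noise_seed = noise$seed)),
    class = "image_pair"
  )
}

#' Generate a clamped-pH calibration image series
#'
#' Emulates in-situ calibration: the imaging buffer is replaced by a series of
#' pH-clamped buffers with ionophores, so every lysosome's true pH equals the
#' buffer pH. Each buffer is imaged in several single-cell fields.
#'
#' @param scene_cfg A [scene_config()] template (its `n_cells` is forced to 1
#'   per calibration field; its `law` supplies the ground truth).
#' @param buffer_phs Strictly monotone buffer pH sequence (default the standard
#'   six-buffer series 7.0, 6.0, 5.0, 4.5, 4.0, 3.0).
#' @param cells_per_buffer Fields imaged per buffer (4 or 5 typically).
#' @param noise A [noise_model()]; per-image seeds are derived from `seed`.
#' @param seed Integer seed for the whole series.
#' @return A list of class `calibration_series`; one element per buffer with
#'   `buffer_ph`, `scenes` (list), `pairs` (list of `image_pair`).
#' @export
make_calibration_series <- function(scene_cfg,
                                    buffer_phs = c(7.0, 6.0, 5.0, 4.5, 4.0, 3.0),
                                    cells_per_buffer = 4,
                                    noise = noise_model(),
                                    seed = 1L) {
  stopifnot(inherits(scene_cfg, "scene_config"))
  if (length(buffer_phs) == 0) stop("buffer_phs must be non-empty")
  if (anyDuplicated(buffer_phs)) stop("duplicate buffer pH values")
  d <- diff(buffer_phs)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("buffer_phs must be strictly increasing or strictly decreasing")
  }
  if (cells_per_buffer < 1) stop("cells_per_buffer must be >= 1")
  out <- vector("list", length(buffer_phs))
  k <- 0L
  for (b in seq_along(buffer_phs)) {
    bph <- buffer_phs[b]
    scenes <- vector("list", cells_per_buffer)
    pairs <- vector("list", cells_per_buffer)
    for (j in seq_len(cells_per_buffer)) {
      k <- k + 1L
      cfg <- scene_cfg
      cfg$n_cells <- 1L
      cfg$condition <- sprintf("calibration_pH%.1f", bph)
      cfg$seed <- derive_seed(seed, k)
      sc <- make_scene(cfg)
      if (nrow(sc$lysosomes)) sc$lysosomes$true_ph <- bph  # ionophore clamp
      nm <- noise
      nm$seed <- derive_seed(seed, 10000L + k)
      scenes[[j]] <- sc
      pairs[[j]] <- render_image_pair(sc, nm)
    }
    out[[b]] <- list(buffer_ph = bph, scenes = scenes, pairs = pairs)
  }
  structure(out, class = "calibration_series")
}

# deterministic 32-bit-safe seed stream
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 104729) %% 2147483647)
}
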