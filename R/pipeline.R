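#' Configuration for a synthetic ratiometric pH experiment
#'
#' Bundles the generator truth (per-condition pH/size distributions, ratio
#' law, noise), the calibration design and all analysis parameters. The
#' defaults describe the reference experiment: a control condition around pH
#' 4.32 with compact puncta, and a treated ("apilimod"-like) condition around
#' pH 4.02 with fewer, swollen lysosomes.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param experiment_id Label carried into all outputs.
#' @param pixel_size_um Physical pixel size, um/px.
#' @param law Ground-truth [ratio_ph_law()] (also the calibration truth).
#' @param noise [noise_model()] shared by all renders.
#' @param conditions Named list; each element is a list with `n_cells`,
#'   `cells_per_scene`, `lysosomes_per_cell`, `radius_mean`, `radius_sd`,
#'   `ph_mean`, `ph_sd`, `image_shape`. The first condition is the control.
#' @param calibration List: `buffer_phs`, `cells_per_buffer`,
#'   `lysosomes_per_cell`, `radius_mean`, `radius_sd`, `image_shape`.
#' @param segmentation [segmentation_params()].
#' @param pairing List with `max_dist_px`, `min_pixel_intensity`.
#' @param min_lysosomes_per_cell Per-cell inclusion floor for summaries.
#' @return A list of class `quantify_config`.
#' @export
quantify_config <- function(
    seed = 1L,
    experiment_id = "synthetic-1",
    pixel_size_um = 0.16,
    law = ratio_ph_law(0.2, 2.0, 4.8, 1.0),
    noise = noise_model(),
    conditions = list(
      control = list(n_cells = 10, cells_per_scene = 2,
                     lysosomes_per_cell = 30, radius_mean = 1.6,
                     radius_sd = 0.25, ph_mean = 4.32, ph_sd = 0.15,
                     image_shape = c(256L, 256L)),
      apilimod = list(n_cells = 10, cells_per_scene = 1,
                      lysosomes_per_cell = 15, radius_mean = 4.9,
                      radius_sd = 0.5, ph_mean = 4.02, ph_sd = 0.15,
                      image_shape = c(320L, 320L))
    ),
    calibration = list(buffer_phs = c(7.0, 6.0, 5.0, 4.5, 4.0, 3.0),
                       cells_per_buffer = 4, lysosomes_per_cell = 12,
                       radius_mean = 1.6, radius_sd = 0.25,
                       image_shape = c(128L, 128L)),
    segmentation = segmentation_params(),
    pairing = list(max_dist_px = 3, min_pixel_intensity = 5),
    min_lysosomes_per_cell = 5) {
  stopifnot(inherits(law, "ratio_ph_law"), inherits(noise, "noise_model"))
  if (length(conditions) < 1 || is.null(names(conditions))) {
    stop("conditions must be a named list; the first entry is the control")
  }
  structure(
    list(seed = as.integer(seed), experiment_id = experiment_id,
         pixel_size_um = pixel_size_um, law = law, noise = noise,
         conditions = conditions, calibration = calibration,
         segmentation = segmentation, pairing = pairing,
         min_lysosomes_per_cell = min_lysosomes_per_cell),
    class = "quantify_config"
  )
}

#' Segment, pair and filter one two-channel image pair
#'
#' Runs the per-image analysis chain: background subtraction, Otsu threshold
#' and component extraction on each channel independently, cross-channel
#' pairing, and the low-intensity pair filter.
#'
#' @param pair An `image_pair`.
#' @param seg [segmentation_params()].
#' @param pairing List with `max_dist_px` and `min_pixel_intensity`.
#' @return Filtered pair table (see [pair_rois()]).
#' @export
process_image_pair <- function(pair, seg = segmentation_params(),
                               pairing = list(max_dist_px = 3,
                                              min_pixel_intensity = 5)) {
  stopifnot(inherits(pair, "image_pair"))
  rois_445 <- segment_channel(pair$ch445, seg, channel = 445L)
  rois_488 <- segment_channel(pair$ch488, seg, channel = 488L)
  p <- pair_rois(rois_445, rois_488, pairing$max_dist_px)
  filter_pairs(p, pairing$min_pixel_intensity)
}

# map pair centroids to scene cells via the ground-truth cell label image;
# centroids falling on background (edge effects) go to the nearest cell center
assign_pairs_to_cells <- function(pairs, scene, cell_id_offset = 0L) {
  if (nrow(pairs) == 0) {
    pairs$cell_id <- integer(0)
    return(pairs)
  }
  lab <- scene$cell_label
  r <- pmin(pmax(round(pairs$centroid_row), 1), nrow(lab))
  c <- pmin(pmax(round(pairs$centroid_col), 1), ncol(lab))
  id <- lab[cbind(r, c)]
  if (any(id == 0) && nrow(scene$cells) > 0) {
    miss <- which(id == 0)
    d <- outer(pairs$centroid_row[miss], scene$cells$center_row, "-")^2 +
      outer(pairs$centroid_col[miss], scene$cells$center_col, "-")^2
    id[miss] <- scene$cells$cell_id[max.col(-d)]
  }
  pairs$cell_id <- id + cell_id_offset
  pairs
}

#' Run the full ratiometric pH quantification on synthetic data
#'
#' Generates a clamped-pH calibration series and per-condition fields from the
#' configuration, then executes the analysis chain on every image pair:
#' background subtraction, Otsu thresholding, component extraction (both
#' channels), cross-channel pairing, low-intensity filtering, calibration
#' fitting, ratio-to-pH inversion, per-cell and per-condition aggregation, the
#' control-vs-treated shift and per-condition pH ECDFs. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [quantify_config()].
#' @param outdir Optional output directory; when given, writes
#'   `lysosomes.csv`, `cells.csv`, `conditions.csv`, `shifts.csv`, `ecdf.csv`,
#'   `calibration.json`, `calibration_points.csv` and `manifest.json`.
#' @return A list: `curve`, `calibration_points`, `measurements`, `cells`,
#'   `conditions`, `shift` (NULL with fewer than two conditions), `ecdf`,
#'   `dropped_cells`, `config`.
#' @export
run_quantify <- function(config = quantify_config(), outdir = NULL) {
  stopifnot(inherits(config, "quantify_config"))
  cal_cfg <- scene_config(
    n_cells = 1L,
    lysosomes_per_cell = config$calibration$lysosomes_per_cell,
    image_shape = config$calibration$image_shape,
    pixel_size_um = config$pixel_size_um,
    radius_mean = config$calibration$radius_mean,
    radius_sd = config$calibration$radius_sd,
    law = config$law, seed = config$seed
  )
  series <- make_calibration_series(
    cal_cfg,
    buffer_phs = config$calibration$buffer_phs,
    cells_per_buffer = config$calibration$cells_per_buffer,
    noise = config$noise,
    seed = derive_seed(config$seed, 1L)
  )
  cal_ph <- numeric(0)
  cal_pairs <- list()
  for (grp in series) {
    for (pair_img in grp$pairs) {
      tab <- process_image_pair(pair_img, config$segmentation, config$pairing)
      if (nrow(tab) == 0) next
      cal_ph <- c(cal_ph, grp$buffer_ph)
      cal_pairs <- c(cal_pairs, list(tab))
    }
  }
  points <- calibration_points(cal_ph, cal_pairs)
  curve <- fit_calibration(points)

  meas_list <- list()
  ecdf_list <- list()
  cond_rows <- list()
  cell_rows <- list()
  dropped <- list()
  scene_counter <- 100L
  for (ci in seq_along(config$conditions)) {
    cname <- names(config$conditions)[ci]
    cc <- config$conditions[[ci]]
    n_scenes <- ceiling(cc$n_cells / cc$cells_per_scene)
    cond_meas <- list()
    cell_offset <- 0L
    for (si in seq_len(n_scenes)) {
      scene_counter <- scene_counter + 1L
      cells_here <- min(cc$cells_per_scene, cc$n_cells - cell_offset)
      sc_cfg <- scene_config(
        n_cells = cells_here,
        lysosomes_per_cell = cc$lysosomes_per_cell,
        image_shape = cc$image_shape,
        pixel_size_um = config$pixel_size_um,
        radius_mean = cc$radius_mean, radius_sd = cc$radius_sd,
        ph_mean = cc$ph_mean, ph_sd = cc$ph_sd,
        law = config$law, condition = cname,
        seed = derive_seed(config$seed, scene_counter)
      )
      scene <- make_scene(sc_cfg)
      nm <- config$noise
      nm$seed <- derive_seed(config$seed, 20000L + scene_counter)
      img <- render_image_pair(scene, nm)
      tab <- process_image_pair(img, config$segmentation, config$pairing)
      tab <- assign_pairs_to_cells(tab, scene, cell_id_offset = cell_offset)
      cond_meas[[si]] <- measure_lysosomes(
        tab, curve, config$pixel_size_um,
        experiment_id = config$experiment_id, condition = cname
      )
      cell_offset <- cell_offset + cells_here
    }
    meas <- do.call(rbind, cond_meas)
    meas$lysosome_id <- seq_len(nrow(meas))
    meas_list[[cname]] <- meas
    sm <- summarize_measurements(meas, config$min_lysosomes_per_cell)
    cell_rows[[cname]] <- cbind(condition = cname, sm$cells)
    cond_rows[[cname]] <- sm$condition
    dropped[[cname]] <- sm$dropped_cells
    ec <- ph_ecdf(meas$ph)
    ecdf_list[[cname]] <- cbind(condition = cname, ec)
  }
  measurements <- do.call(rbind, meas_list)
  rownames(measurements) <- NULL
  cells <- do.call(rbind, cell_rows)
  rownames(cells) <- NULL
  conditions <- do.call(rbind, cond_rows)
  rownames(conditions) <- NULL
  ecdf_tab <- do.call(rbind, ecdf_list)
  rownames(ecdf_tab) <- NULL

  shift <- NULL
  if (nrow(conditions) >= 2) {
    shift <- ph_shift(conditions[1, , drop = FALSE],
                      conditions[2, , drop = FALSE])
  }
  out <- list(curve = curve, calibration_points = points,
              measurements = measurements, cells = cells,
              conditions = conditions, shift = shift, ecdf = ecdf_tab,
              dropped_cells = dropped, config = config)
  if (!is.null(outdir)) write_quantify_outputs(out, outdir)
  out
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config), tmp)
  unname(tools::md5sum(tmp))
}

write_quantify_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.csv(format(x, digits = 9, trim = TRUE, scientific = FALSE),
                     file.path(outdir, name), row.names = FALSE, quote = FALSE)
  }
  wr(res$measurements, "lysosomes.csv")
  wr(res$cells, "cells.csv")
  wr(res$conditions, "conditions.csv")
  if (!is.null(res$shift)) wr(res$shift, "shifts.csv")
  wr(res$ecdf, "ecdf.csv")
  write_calibration(res$curve, res$calibration_points, outdir)
  jsonlite::write_json(
    list(seed = res$config$seed, config_hash = config_hash(res$config),
         package_version = as.character(utils::packageVersion("lysoratio")),
         n_lysosomes = nrow(res$measurements), n_cells = nrow(res$cells),
         n_conditions = nrow(res$conditions)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}

#' Configuration for a synthetic break-in inhibition experiment
#'
#' @param seed Master seed.
#' @param gating [gating_params()] of the simulated transporter.
#' @param inhibition [inhibition_model()].
#' @param protocol [ephys_protocol()].
#' @param concentrations_um Pipette concentrations simulated (uM).
#' @param n_cells_per_conc Cells (early/late recording pairs) per
#'   concentration.
#' @param t_early_s,t_late_s Break-in times of the early and late recordings.
#' @param noise_sd_pa Additive current noise, pA.
#' @param v_ref_mv Reference voltage for the metrics.
#' @param g_max_cv Lognormal coefficient of variation of per-cell conductance.
#' @return A list of class `ephys_config`.
#' @export
ephys_config <- function(seed = 1L,
                         gating = gating_params(),
                         inhibition = inhibition_model(),
                         protocol = ephys_protocol(),
                         concentrations_um = c(0, 25, 50, 100),
                         n_cells_per_conc = 5,
                         t_early_s = 30, t_late_s = 180,
                         noise_sd_pa = 10,
                         v_ref_mv = 140,
                         g_max_cv = 0.2) {
  stopifnot(inherits(gating, "gating_params"),
            inherits(inhibition, "inhibition_model"))
  if (any(concentrations_um < 0)) stop("concentrations must be >= 0")
  if (t_late_s <= t_early_s) stop("t_late_s must exceed t_early_s")
  structure(
    list(seed = as.integer(seed), gating = gating, inhibition = inhibition,
         protocol = protocol, concentrations_um = concentrations_um,
         n_cells_per_conc = n_cells_per_conc, t_early_s = t_early_s,
         t_late_s = t_late_s, noise_sd_pa = noise_sd_pa, v_ref_mv = v_ref_mv,
         g_max_cv = g_max_cv),
    class = "ephys_config"
  )
}

#' Run the break-in inhibition analysis on simulated cells
#'
#' For each concentration and cell, simulates an early and a late sweep family
#' (same cell-specific conductance), computes [family_metrics()] and
#' [inhibition_ratio()], aggregates per concentration and — given at least 4
#' distinct concentrations — fits a Hill dose-response to the per-cell
#' fractional inhibition `1 - max_ratio` with the floor pinned at 0 (the
#' zero-dose arm is a true blank).
#'
#' @param config An [ephys_config()].
#' @param outdir Optional directory for `ephys_metrics.csv`,
#'   `ephys_summary.csv`, `dose_response.json`, `manifest.json`.
#' @return A list: `metrics` (per cell), `summary` (per concentration),
#'   `dose_fit` (or NULL), `config`.
#' @export
run_ephys <- function(config = ephys_config(), outdir = NULL) {
  stopifnot(inherits(config, "ephys_config"))
  rows <- list()
  k <- 0L
  for (conc in config$concentrations_um) {
    for (cell in seq_len(config$n_cells_per_conc)) {
      k <- k + 1L
      set.seed(derive_seed(config$seed, 500L + k))
      g <- config$gating
      if (config$g_max_cv > 0) {
        sdlog <- sqrt(log(1 + config$g_max_cv^2))
        g$g_max <- g$g_max * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      }
      fam_early <- simulate_family(
        g, config$inhibition, conc, config$t_early_s, config$protocol,
        noise_sd = config$noise_sd_pa, seed = derive_seed(config$seed, 1000L + k)
      )
      fam_late <- simulate_family(
        g, config$inhibition, conc, config$t_late_s, config$protocol,
        noise_sd = config$noise_sd_pa, seed = derive_seed(config$seed, 2000L + k)
      )
      me <- family_metrics(fam_early, config$v_ref_mv)
      rat <- inhibition_ratio(fam_late, fam_early, config$v_ref_mv)
      rows[[k]] <- data.frame(
        conc_um = conc, cell = cell,
        i_max_early_pa = me$i_max, i_tail_early_pa = me$i_tail,
        tau_act_s = me$tau_act, tau_deact_s = me$tau_deact,
        max_ratio = rat$max_ratio, tail_ratio = rat$tail_ratio
      )
    }
  }
  metrics <- do.call(rbind, rows)
  agg <- function(v) tapply(v, metrics$conc_um, mean)
  summary <- data.frame(
    conc_um = as.numeric(names(agg(metrics$max_ratio))),
    n_cells = as.integer(tapply(metrics$cell, metrics$conc_um, length)),
    mean_max_ratio = as.numeric(agg(metrics$max_ratio)),
    mean_tail_ratio = as.numeric(agg(metrics$tail_ratio)),
    mean_tau_act_s = as.numeric(agg(metrics$tau_act_s)),
    mean_tau_deact_s = as.numeric(agg(metrics$tau_deact_s))
  )
  dose_fit <- NULL
  if (length(unique(metrics$conc_um)) >= 4) {
    dose_fit <- fit_dose_response(metrics$conc_um, 1 - metrics$max_ratio,
                                  fix_floor = 0)
  }
  out <- list(metrics = metrics, summary = summary, dose_fit = dose_fit,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(outdir, "ephys_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(outdir, "ephys_summary.csv"),
                     row.names = FALSE)
    if (!is.null(dose_fit)) {
      jsonlite::write_json(unclass(dose_fit),
                           file.path(outdir, "dose_response.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      list(seed = config$seed, config_hash = config_hash(config),
           package_version = as.character(utils::packageVersion("lysoratio")),
           n_cells = nrow(metrics)),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}
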