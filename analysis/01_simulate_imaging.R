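#!/usr/bin/env Rscript

# Step 1 — simulate a dual-excitation imaging experiment.
#
# Renders a control vs apilimod-like experiment (two-channel TIFFs) together
# with its clamped-pH calibration series and the ground-truth lysosome table,
# so the downstream quantification steps can be run on files on disk exactly
# as they would be on exported microscope data.

suppressMessages(library(lysoratio))

seed <- 20260923L
out <- "results/simulated_imaging"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- quantify_config(seed = seed)
noise <- cfg$noise

message("Rendering condition fields ...")
scenes <- list()
k <- 0L
for (cname in names(cfg$conditions)) {
  cc <- cfg$conditions[[cname]]
  n_scenes <- ceiling(cc$n_cells / cc$cells_per_scene)
  for (si in seq_len(n_scenes)) {
    k <- k + 1L
    sc <- make_scene(scene_config(
      n_cells = min(cc$cells_per_scene, cc$n_cells),
      lysosomes_per_cell = cc$lysosomes_per_cell,
      image_shape = cc$image_shape, pixel_size_um = cfg$pixel_size_um,
      radius_mean = cc$radius_mean, radius_sd = cc$radius_sd,
      ph_mean = cc$ph_mean, ph_sd = cc$ph_sd, law = cfg$law,
      condition = cname, seed = seed + k
    ))
    nm <- noise
    nm$seed <- seed + 1000L + k
    img <- render_image_pair(sc, nm)
    write_image_pair(img, out, condition = cname, cell_id = si)
    scenes[[k]] <- sc
  }
}
write_scene_truth(scenes, noise, out)

message("Rendering calibration series (6 buffers x 4 cells) ...")
cal_dir <- file.path(out, "calibration")
ser <- make_calibration_series(
  scene_config(n_cells = 1,
               lysosomes_per_cell = cfg$calibration$lysosomes_per_cell,
               image_shape = cfg$calibration$image_shape,
               pixel_size_um = cfg$pixel_size_um, law = cfg$law),
  buffer_phs = cfg$calibration$buffer_phs,
  cells_per_buffer = cfg$calibration$cells_per_buffer,
  noise = noise, seed = seed + 5000L
)
for (grp in ser) {
  for (j in seq_along(grp$pairs)) {
    write_image_pair(grp$pairs[[j]], cal_dir,
                     condition = sprintf("pH%.1f", grp$buffer_ph), cell_id = j)
  }
}

n_tif <- length(list.files(out, pattern = "\\.tif$", recursive = TRUE))
message("Wrote ", n_tif, " TIFFs plus ground truth under ", out)
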