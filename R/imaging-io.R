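#' Write an image pair as 16-bit grayscale TIFFs
#'
#' Files are named `{condition}__cell{ID}__{445|488}.tif`. Counts are rounded
#' to integers and clipped to \[0, 65535\] (16-bit quantization).
#'
#' @param pair An `image_pair`.
#' @param dir Output directory (created if needed).
#' @param condition,cell_id Used to build the file names; `condition` defaults
#'   to the pair's label.
#' @return Invisibly, the two file paths (445 then 488).
#' @export
write_image_pair <- function(pair, dir, condition = NULL, cell_id = 1L) {
  stopifnot(inherits(pair, "image_pair"))
  if (is.null(condition)) condition <- pair$labels$condition
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s__cell%s__%d.tif", condition, cell_id,
                                  c(445L, 488L)))
  for (i in 1:2) {
    img <- if (i == 1) pair$ch445 else pair$ch488
    q <- pmin(pmax(round(img), 0), 65535) / 65535
    tiff::writeTIFF(q, paths[i], bits.per.sample = 16, compression = "none")
  }
  invisible(paths)
}

#' Read a two-channel TIFF image pair
#'
#' @param path_445,path_488 Paths to the 16-bit grayscale TIFFs.
#' @param pixel_size_um Physical pixel size (not stored in the TIFFs).
#' @param condition Optional label.
#' @return An `image_pair` with counts on the original scale.
#' @export
read_image_pair <- function(path_445, path_488, pixel_size_um,
                            condition = "unknown") {
  rd <- function(p) {
    if (!file.exists(p)) stop("image file not found: ", p)
    m <- tiff::readTIFF(p)
    if (length(dim(m)) != 2) stop("expected single-channel grayscale TIFF: ", p)
    round(m * 65535)
  }
  ch445 <- rd(path_445)
  ch488 <- rd(path_488)
  if (!all(dim(ch445) == dim(ch488))) {
    stop("channel shapes differ: ", path_445, " vs ", path_488)
  }
  structure(
    list(ch445 = ch445, ch488 = ch488, pixel_size_um = pixel_size_um,
         labels = list(condition = condition)),
    class = "image_pair"
  )
}

#' Write scene ground truth (lysosome table + generator sidecar)
#'
#' `truth_lysosomes.csv` holds one row per lysosome (scene, cell_id,
#' lysosome_id, row, col, radius_px, true_ph); `truth_meta.json` records the
#' ratio law, noise model and seeds.
#'
#' @param scenes List of `synthetic_scene` objects (or a single scene).
#' @param noise The [noise_model()] used for rendering.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_scene_truth <- function(scenes, noise, dir) {
  if (inherits(scenes, "synthetic_scene")) scenes <- list(scenes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    if (nrow(s$lysosomes) == 0) return(NULL)
    cbind(scene = i, condition = s$condition,
          s$lysosomes[, c("cell_id", "lysosome_id", "row", "col",
                          "radius_px", "true_ph")])
  }))
  csv_path <- file.path(dir, "truth_lysosomes.csv")
  json_path <- file.path(dir, "truth_meta.json")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  law <- scenes[[1]]$law
  jsonlite::write_json(
    list(
      law = list(r_min = law$r_min, r_max = law$r_max, ph50 = law$ph50,
                 slope_h = law$slope_h),
      noise = list(background_level = noise$background_level,
                   gradient_amplitude = noise$gradient_amplitude,
                   read_noise_sd = noise$read_noise_sd,
                   photon_scale = noise$photon_scale,
                   shot_noise = noise$shot_noise, seed = noise$seed),
      scene_seeds = vapply(scenes, function(s) s$seed, integer(1)),
      pixel_size_um = scenes[[1]]$pixel_size_um
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv_path, json_path))
}
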