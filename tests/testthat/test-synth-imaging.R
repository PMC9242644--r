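test_that("scene generation handles the empty case and validates inputs", {
  sc <- make_scene(scene_config(n_cells = 0, seed = 1))
  expect_equal(nrow(sc$cells), 0)
  expect_equal(nrow(sc$lysosomes), 0)
  expect_true(all(sc$cell_label == 0))

  expect_error(scene_config(image_shape = c(0, 64)), "image_shape")
  expect_error(scene_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(scene_config(radius_mean = -1), "radius")
})

test_that("scene generation is deterministic and seed-sensitive", {
  cfg <- scene_config(n_cells = 2, lysosomes_per_cell = 5, seed = 1)
  expect_identical(make_scene(cfg), make_scene(cfg))

  cfg2 <- cfg
  cfg2$seed <- 2L
  expect_false(identical(make_scene(cfg)$lysosomes, make_scene(cfg2)$lysosomes))

  nm <- noise_model(seed = 7)
  sc <- make_scene(cfg)
  expect_identical(render_image_pair(sc, nm), render_image_pair(sc, nm))
  nm2 <- nm
  nm2$seed <- 8L
  expect_false(identical(render_image_pair(sc, nm)$ch445,
                         render_image_pair(sc, nm2)$ch445))
})

test_that("scene invariants hold: lysosomes inside cells, pH truncated", {
  sc <- make_scene(scene_config(n_cells = 3, lysosomes_per_cell = 10,
                                image_shape = c(200, 200), ph_mean = 4.3,
                                ph_sd = 1.5, seed = 4))
  lys <- sc$lysosomes
  expect_false(anyDuplicated(lys$lysosome_id) > 0)
  expect_true(all(lys$true_ph >= 3.0 & lys$true_ph <= 7.5))
  inside <- sc$cell_label[cbind(round(lys$row), round(lys$col))]
  expect_equal(inside, lys$cell_id)
})

test_that("true pH draws follow the configured truncated Normal", {
  cfg <- scene_config(n_cells = 50, lysosomes_per_cell = 20,
                      image_shape = c(1200, 1200), ph_mean = 4.32,
                      ph_sd = 0.15, seed = 7)
  ph <- make_scene(cfg)$lysosomes$true_ph
  expect_length(ph, 1000)
  # truncation at [3, 7.5] is ~9 sd away: the mean is that of the Normal
  expect_lt(abs(mean(ph) - 4.32), 3 * 0.15 / sqrt(1000))
  # independent draws from the same generator agree in distribution
  set.seed(99)
  direct <- qnorm(runif(20000, pnorm(3, 4.32, 0.15), pnorm(7.5, 4.32, 0.15)),
                  4.32, 0.15)
  expect_lt(abs(mean(ph) - mean(direct)), 0.02)
  expect_lt(abs(sd(ph) - sd(direct)), 0.02)
})

test_that("noiseless renders satisfy the exact ratio identity", {
  law <- ratio_ph_law(0.2, 2.0, 4.8, 1.0)
  for (ph in c(4.8, 5.8, 3.6)) {
    sc <- make_scene(scene_config(n_cells = 1, lysosomes_per_cell = 1,
                                  image_shape = c(64, 64), ph_mean = ph,
                                  ph_sd = 0, law = law, seed = 2))
    img <- render_image_pair(sc, noiseless_noise_model())
    ratio <- sum(img$ch488) / sum(img$ch445)
    expect_equal(ratio, ratio_from_ph(law, ph), tolerance = 1e-9)
  }
  # hand-computed value: R(5.8) = 0.2 + 1.8 / (1 + 10^(4.8 - 5.8)) = 1.83636...
  sc <- make_scene(scene_config(n_cells = 1, lysosomes_per_cell = 1,
                                image_shape = c(64, 64), ph_mean = 5.8,
                                ph_sd = 0, law = law, seed = 2))
  img <- render_image_pair(sc, noiseless_noise_model())
  expect_equal(sum(img$ch488) / sum(img$ch445), 0.2 + 1.8 / 1.1,
               tolerance = 1e-9)
})

test_that("the 445 reference channel is independent of true pH", {
  mk <- function(ph) {
    sc <- make_scene(scene_config(n_cells = 1, lysosomes_per_cell = 4,
                                  image_shape = c(96, 96), ph_mean = ph,
                                  ph_sd = 0, seed = 5))
    render_image_pair(sc, noiseless_noise_model())$ch445
  }
  expect_identical(mk(3.5), mk(6.5))
})

test_that("calibration series clamps pH, groups cells and is monotone", {
  cfg <- scene_config(n_cells = 1, lysosomes_per_cell = 6,
                      image_shape = c(96, 96), ph_mean = 4.3, ph_sd = 0.3)
  expect_error(make_calibration_series(cfg, buffer_phs = c(5, 5)), "duplicate")
  expect_error(make_calibration_series(cfg, buffer_phs = c(5, 7, 6)),
               "strictly")
  expect_error(make_calibration_series(cfg, buffer_phs = numeric(0)),
               "non-empty")

  ser <- make_calibration_series(cfg, cells_per_buffer = 4,
                                 noise = noiseless_noise_model(), seed = 3)
  expect_length(ser, 6)
  expect_equal(vapply(ser, function(g) length(g$pairs), integer(1)),
               rep(4L, 6))
  for (g in ser) {
    for (sc in g$scenes) expect_true(all(sc$lysosomes$true_ph == g$buffer_ph))
  }
  # per-buffer mean spot ratio strictly increases with buffer pH
  mean_ratio <- vapply(ser, function(g) {
    mean(vapply(g$pairs, function(p) sum(p$ch488) / sum(p$ch445), numeric(1)))
  }, numeric(1))
  ph <- vapply(ser, function(g) g$buffer_ph, numeric(1))
  expect_true(all(diff(mean_ratio[order(ph)]) > 0))

  # midpoint clamp: every spot ratio equals (r_min + r_max) / 2
  ser48 <- make_calibration_series(cfg, buffer_phs = 4.8, cells_per_buffer = 2,
                                   noise = noiseless_noise_model(), seed = 3)
  for (p in ser48[[1]]$pairs) {
    expect_equal(sum(p$ch488) / sum(p$ch445), 1.1, tolerance = 1e-9)
  }
})

test_that("image pairs survive a 16-bit TIFF round trip", {
  sc <- tiny_scene(seed = 6)
  img <- render_image_pair(sc, noise_model(seed = 6))
  img$ch445 <- round(img$ch445)
  img$ch488 <- round(img$ch488)
  dir <- withr::local_tempdir()
  paths <- write_image_pair(img, dir, condition = "demo", cell_id = 1)
  back <- read_image_pair(paths[1], paths[2], pixel_size_um = 0.16)
  expect_equal(back$ch445, img$ch445, ignore_attr = TRUE)
  expect_equal(back$ch488, img$ch488, ignore_attr = TRUE)
  truth <- write_scene_truth(sc, noise_model(seed = 6), dir)
  tab <- read.csv(truth[1])
  expect_equal(nrow(tab), nrow(sc$lysosomes))
  expect_true(all(c("cell_id", "lysosome_id", "row", "col", "radius_px",
                    "true_ph") %in% names(tab)))
})
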