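test_that("background subtraction removes flat and ramp backgrounds", {
  expect_equal(subtract_background(matrix(7.5, 40, 40), 5),
               matrix(0, 40, 40))

  # isolated bright pixel on zero background is preserved
  img <- matrix(0, 40, 40)
  img[20, 20] <- 42
  expect_equal(subtract_background(img, 5)[20, 20], 42, tolerance = 1e-3)

  # linear ramp plus a Gaussian spot: spot peak recovered within 5%
  ramp <- outer(seq(0, 50, length.out = 96), seq(0, 30, length.out = 96), "+")
  d2 <- outer((1:96 - 48)^2, (1:96 - 48)^2, "+")
  spot <- 100 * exp(-d2 / (2 * 2^2))
  rec <- subtract_background(ramp + spot, 15)[48, 48]
  expect_lt(abs(rec - 100) / 100, 0.05)

  expect_error(subtract_background(matrix(0, 10, 10), 6), "half")
  expect_error(subtract_background(matrix(0, 10, 10), 0.5), ">= 1")
})

test_that("otsu threshold matches hand-worked examples", {
  # four zeros and two tens: lowest maximizing split keeps the zeros below
  thr <- otsu_threshold(matrix(c(0, 0, 0, 0, 10, 10), 2, 3))
  expect_equal(thr, 0)
  v <- c(0, 0, 0, 0, 10, 10)
  expect_equal(sum(v > thr), 2)

  # a single bright pixel separates as foreground
  img <- matrix(0, 8, 8)
  img[3, 5] <- 255
  expect_true(all(which(img > otsu_threshold(img)) == which(img == 255)))

  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(42)
  for (i in 1:150) {
    v <- sample.int(256, 48, replace = TRUE) - 1
    if (min(v) == max(v)) next
    thr <- otsu_threshold(matrix(v, 6, 8))
    expect_identical(v > thr, brute_force_otsu_mask(v))
  }
})

test_that("extract_rois enumerates components as hand-constructed", {
  img <- matrix(0, 20, 20)
  img[3:5, 3:5] <- 100
  img[12:14, 13:15] <- 100
  rois <- extract_rois(img, threshold = 50, min_area = 4)
  expect_equal(nrow(rois), 2)
  expect_equal(rois$area_px, c(9L, 9L))
  expect_equal(rois$mean_intensity, c(100, 100))
  expect_equal(rois$centroid_row, c(4, 13))
  expect_equal(rois$centroid_col, c(4, 14))

  # empty foreground
  expect_equal(nrow(extract_rois(matrix(0, 5, 5), 1)), 0)

  # diagonal pair: one component under 8-connectivity, none at min_area 2
  # under 4-connectivity
  dimg <- matrix(0, 6, 6)
  dimg[2, 2] <- 5
  dimg[3, 3] <- 5
  r8 <- extract_rois(dimg, 1, min_area = 2, connectivity = 8)
  expect_equal(nrow(r8), 1)
  expect_equal(r8$area_px, 2L)
  r4 <- extract_rois(dimg, 1, min_area = 2, connectivity = 4)
  expect_equal(nrow(r4), 0)
})

test_that("ROIs are disjoint and cover the filtered foreground", {
  set.seed(3)
  img <- matrix(rpois(64 * 64, 1), 64, 64)
  img[10:14, 10:14] <- 40
  img[40:46, 30:38] <- 35
  thr <- otsu_threshold(img)
  rois <- extract_rois(img, thr, min_area = 4)
  px <- unlist(rois$pixels)
  expect_false(anyDuplicated(px) > 0)
  lab <- label_set <- which(img > thr)
  # every retained pixel is foreground; dropped foreground only from small
  # components
  expect_true(all(px %in% label_set))
  expect_true(all(img[px] > thr))
})

test_that("noiseless scenes are recovered spot-for-spot", {
  sc <- tiny_scene(n_lysosomes = 8, ph_mean = 4.5, seed = 11,
                   shape = c(128L, 128L))
  img <- render_image_pair(sc, noiseless_noise_model())
  rois <- segment_channel(img$ch445, segmentation_params(), channel = 445L)
  expect_equal(nrow(rois), 8)
  d <- sqrt(outer(rois$centroid_row, sc$lysosomes$row, "-")^2 +
            outer(rois$centroid_col, sc$lysosomes$col, "-")^2)
  expect_true(all(apply(d, 1, min) < 1))
})
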