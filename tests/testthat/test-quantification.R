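curve48 <- exact_curve()

make_pairs <- function(ratios, areas_px = 25, cell_id = 1L) {
  n <- length(ratios)
  data.frame(
    cell_id = cell_id,
    area_px_445 = rep_len(areas_px, n),
    mean_intensity_445 = 100,
    mean_intensity_488 = 100 * ratios,
    min_intensity_445 = 50, min_intensity_488 = 50,
    ratio = ratios
  )
}

test_that("measurement records carry inverted pH and physical area", {
  m <- measure_lysosomes(make_pairs(1.1, areas_px = 25), curve48,
                         pixel_size_um = 0.1)
  expect_equal(m$ph, 4.8)
  expect_equal(m$area_um2, 0.25)
  expect_false(m$clamped)

  m2 <- measure_lysosomes(make_pairs(2.5), curve48, 0.1)
  expect_true(m2$clamped)
  expect_equal(m2$ph, 7)
})

test_that("noiseless synthetic cells measure at their clamped pH", {
  sc <- make_scene(scene_config(n_cells = 1, lysosomes_per_cell = 8,
                                image_shape = c(128, 128), ph_mean = 4.5,
                                ph_sd = 0, seed = 13))
  img <- render_image_pair(sc, noiseless_noise_model())
  tab <- process_image_pair(img)
  m <- measure_lysosomes(tab, curve48, 0.16, cell_id = 1L)
  expect_equal(nrow(m), 8)
  expect_true(all(abs(m$ph - 4.5) < 0.01))
})

test_that("summaries aggregate lysosomes to cells to conditions", {
  meas <- rbind(
    measure_lysosomes(make_pairs(c(rep(1.1, 3), rep(1.1, 2)), cell_id = 1L),
                      curve48, 0.1),
    measure_lysosomes(make_pairs(rep(1.1, 5), cell_id = 2L), curve48, 0.1)
  )
  # engineer cell means 4.1 and 4.3 via known ratios
  meas$ph <- c(4.0, 4.1, 4.2, 4.05, 4.15, rep(4.3, 5))
  sm <- summarize_measurements(meas, min_lysosomes_per_cell = 5)
  expect_equal(sm$cells$mean_ph, c(4.1, 4.3))
  expect_equal(sm$condition$mean_ph, 4.2)
  # SEM of {4.1, 4.3}: sd = 0.1414..., / sqrt(2) = 0.1
  expect_equal(sm$condition$sem_ph, 0.1, tolerance = 1e-9)

  # a one-cell mean is the plain average
  one <- meas[meas$cell_id == 1, ][1:2, ]
  one$ph <- c(4.0, 4.4)
  sm1 <- summarize_measurements(one, min_lysosomes_per_cell = 2)
  expect_equal(sm1$cells$mean_ph, 4.2)

  # permutation invariance
  perm <- meas[sample(nrow(meas)), ]
  expect_equal(summarize_measurements(perm, 5)$condition,
               sm$condition)

  # cells below the floor are excluded; all below floor is an error
  expect_error(summarize_measurements(meas, min_lysosomes_per_cell = 50),
               "lysosomes")
})

test_that("shift and proton fold-change follow the sign convention", {
  expect_equal(proton_fold_change(0), 1)
  expect_equal(proton_fold_change(-1), 10)
  expect_equal(proton_fold_change(-0.31), 10^0.31)
  # treated more acidic than control by 0.31 -> ~2.04-fold more protons
  ctl <- data.frame(condition = "control", mean_ph = 4.32,
                    mean_area_um2 = 0.5)
  trt <- data.frame(condition = "apilimod", mean_ph = 4.01,
                    mean_area_um2 = 4.5)
  sh <- ph_shift(ctl, trt)
  expect_equal(sh$delta_ph, -0.31)
  expect_equal(sh$proton_fold, 2.0417, tolerance = 1e-4)
  expect_equal(sh$delta_area_um2, 4.0)
})

test_that("proton fold obeys the reciprocal identity", {
  x <- c(-1, -0.31, -0.05, 0, 0.13, 0.7)
  expect_equal(proton_fold_change(x) * proton_fold_change(-x), rep(1, 6))
})

test_that("the pH ECDF is a proper right-continuous CDF", {
  e <- ph_ecdf(c(4.0, 4.5, 4.5, 5.0))
  expect_equal(e$fraction[e$ph == 4.5], 0.75)
  expect_equal(e$fraction[length(e$fraction)], 1)
  expect_true(all(diff(e$fraction) > 0))
  expect_equal(ph_ecdf(4.2), data.frame(ph = 4.2, fraction = 1))
  expect_error(ph_ecdf(numeric(0)), "empty")
})

test_that("pH-size correlation matches hand computation and null case", {
  # {(1,1),(2,2),(3,2)}: r = 0.5 / (1 * 0.57735) = 0.866
  m <- data.frame(ph = c(1, 2, 3), area_um2 = c(1, 2, 2))
  ct <- ph_size_correlation(m)
  expect_equal(ct$r, 0.8660254, tolerance = 1e-6)

  expect_error(ph_size_correlation(data.frame(ph = c(1, 1, 1),
                                              area_um2 = 1:3)), "variance")

  # independent by construction: |r| below 2.5/sqrt(n)
  set.seed(8)
  m2 <- data.frame(ph = rnorm(1000, 4.3, 0.2),
                   area_um2 = rlnorm(1000, -0.5, 0.4))
  expect_lt(abs(ph_size_correlation(m2)$r), 0.08)

  # perfectly linear relation gives r = 1
  m3 <- data.frame(ph = 1:10, area_um2 = 2 * (1:10) + 3)
  expect_equal(ph_size_correlation(m3)$r, 1)
})

test_that("two-sample tests reproduce closed-form Student's t", {
  # pooled-variance oracle for a = 1:3, b = 4:6
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_manual <- 2 * pt(abs(t_manual), df = 4, lower.tail = FALSE)
  res <- two_sample_test(a, b)
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$t, -3.6742, tolerance = 1e-4)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0213, tolerance = 2e-3)
  expect_equal(res$df, 4)

  # identical samples: t = 0, p = 1
  res0 <- two_sample_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)

  # paired differences {1, -1}: zero mean difference
  resp <- two_sample_test(c(2, 1), c(1, 2), paired = TRUE)
  expect_equal(resp$t, 0)
  expect_equal(resp$p_value, 1)

  expect_error(two_sample_test(c(1, 1), c(2, 2)), "degenerate")
  expect_error(two_sample_test(c(1, 2), c(1, 2, 3), paired = TRUE), "equal")
  expect_error(two_sample_test(1, c(1, 2)), ">= 2")
})
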