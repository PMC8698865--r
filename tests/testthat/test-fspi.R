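test_that("pixel-scale calibration matches direct division and rejects bad input", {
  expect_lt(abs(pixel_scale(48, 5396) - 88.9), 0.1)
  expect_equal(pixel_scale(1, 100), 100)
  expect_equal(pixel_scale(12, 1349), 12e4 / 1349)
  expect_error(pixel_scale(0, 100), "positive")
  expect_error(pixel_scale(10, -1), "positive")
})

test_that("side merging concatenates widths and validates geometry", {
  sides <- lapply(1:4, function(i) array(i / 10, dim = c(20, 1349, 3)))
  merged <- merge_sides(sides)
  expect_equal(dim(merged), c(20, 5396, 3))
  blank <- lapply(1:4, function(i) array(0, dim = c(10, 5, 3)))
  expect_true(all(merge_sides(blank) == 0))
  bad <- sides
  bad[[2]] <- array(0, dim = c(21, 1349, 3))
  expect_error(merge_sides(bad), "height")
  expect_error(merge_sides(sides[1:3][c(1, 2, 3, NA)]), "missing")
})

test_that("point-source truth yields exact unit depth metrics", {
  truth <- render_fspi_image(width_px = 120, height_px = 320, pixel_scale = 100,
                             depth_law = depth_law("point", depth_cm = 1),
                             interface = interface_law("flat"),
                             n_luminophore_px = 1, seed = 1)
  tm <- truth_metrics(truth)
  expect_equal(tm$L_mean, 1)
  expect_equal(tm$L_median, 1)
  expect_equal(tm$L_max, 1)
  expect_equal(tm$SBR, 0)
})

test_that("uniform-law truth matches analytic moments within Monte-Carlo error", {
  law <- depth_law("uniform", max_cm = 2)
  truth <- render_fspi_image(width_px = 400, height_px = 500, pixel_scale = 100,
                             depth_law = law, n_luminophore_px = 1e4, seed = 2)
  tm <- truth_metrics(truth)
  mom <- depth_law_moments(law)
  se <- (mom$max_cm / sqrt(12)) / sqrt(1e4)
  expect_lt(abs(tm$L_mean - mom$mean_cm), 3 * se)
  expect_lt(abs(tm$L_max - mom$max_cm), 0.01)  # 1 px at 100 um/px
})

test_that("step interface gives exact surface boundary roughness", {
  truth <- render_fspi_image(width_px = 200, height_px = 400, pixel_scale = 100,
                             depth_law = depth_law("surface"),
                             interface = interface_law("step", h1_cm = 0, h2_cm = 0.5),
                             n_luminophore_px = 500, seed = 3)
  expect_equal(truth_metrics(truth)$SBR, 0.5)
})

test_that("images are byte-identical under the same seed", {
  args <- list(width_px = 100, height_px = 200, pixel_scale = 200,
               n_luminophore_px = 300, seed = 9)
  t1 <- do.call(render_fspi_image, args)
  t2 <- do.call(render_fspi_image, args)
  expect_identical(t1$image, t2$image)
  expect_identical(t1$label_mask, t2$label_mask)
})

test_that("depths beyond the sediment column are rejected with a message", {
  expect_error(
    render_fspi_image(width_px = 50, height_px = 250, pixel_scale = 100,
                      interface_depth_cm = 1,
                      depth_law = depth_law("point", depth_cm = 5),
                      n_luminophore_px = 10, seed = 1),
    "exceeds the image height"
  )
})

test_that("segmentation is exact on noise-free images and empty on background", {
  truth <- render_fspi_image(width_px = 150, height_px = 250, pixel_scale = 200,
                             n_luminophore_px = 800, seed = 4)
  mask <- segment_luminophores(truth$image)
  expect_equal(unclass(mask), unclass(truth$label_mask))
  blank <- render_fspi_image(width_px = 50, height_px = 80, pixel_scale = 400,
                             n_luminophore_px = 0, seed = 5)
  expect_equal(sum(segment_luminophores(blank$image)), 0)
  expect_error(segment_luminophores(array(0, dim = c(0, 0, 3))), "non-empty")
})

test_that("segmentation stays accurate under speckle and luminance noise", {
  truth <- render_fspi_image(width_px = 300, height_px = 400, pixel_scale = 200,
                             n_luminophore_px = 3000,
                             noise = list(salt_pepper = 0.002, gauss_sd = 0.03),
                             seed = 6)
  mask <- segment_luminophores(truth$image)
  tp <- sum(mask == 1L & truth$label_mask == 1L)
  fp <- sum(mask == 1L & truth$label_mask == 0L)
  fn <- sum(mask == 0L & truth$label_mask == 1L)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.95)
})

test_that("interface tracing recovers flat, step and jittered-sinusoid surfaces", {
  flat <- render_fspi_image(width_px = 100, height_px = 200, pixel_scale = 200,
                            n_luminophore_px = 0, seed = 7)
  prof <- detect_interface(flat$image)
  expect_equal(length(unique(prof$elevation_row)), 1L)
  expect_equal(prof$elevation_row, flat$interface_row, ignore_attr = TRUE)

  step <- render_fspi_image(width_px = 100, height_px = 300, pixel_scale = 100,
                            interface = interface_law("step", h1_cm = 0, h2_cm = 0.57),
                            n_luminophore_px = 0, seed = 7)
  p2 <- detect_interface(step$image, smoothing_window = 1)
  expect_equal(max(p2$elevation_row) - min(p2$elevation_row), 57)

  sine <- render_fspi_image(width_px = 400, height_px = 300, pixel_scale = 100,
                            interface = interface_law("sinusoid", amplitude_cm = 0.3,
                                                      period_cm = 4, jitter_px = 1),
                            n_luminophore_px = 0, seed = 8)
  p3 <- detect_interface(sine$image)
  expect_lte(max(abs(p3$elevation_row - sine$interface_row)), 2)
})

test_that("depth metrics follow the per-column flooring and null-result rules", {
  m <- matrix(0L, 30, 10)
  interface <- rep(10, 10)
  m[20, 4] <- 1L  # 10 px below the interface
  one <- depth_metrics(m, interface, pixel_scale = 1000)  # 1 px = 0.1 cm
  expect_equal(one$L_mean, 1)
  expect_equal(one$L_median, 1)
  expect_equal(one$L_max, 1)
  expect_equal(one$SBR, 0)

  above <- matrix(0L, 30, 10)
  above[c(3, 5), 2] <- 1L  # strictly above the interface
  res <- depth_metrics(above, interface, 1000)
  expect_equal(res$L_mean, 0)
  expect_equal(res$L_max, 0)

  empty <- depth_metrics(matrix(0L, 30, 10), interface, 1000)
  expect_equal(empty$n_pixels, 0L)
  expect_true(is.na(empty$L_mean) && is.na(empty$L_max))
})

test_that("SBR aggregation averages sides and rejects empty input", {
  expect_equal(aggregate_sbr(c(1, 1, 1, 1)), 1)
  expect_equal(aggregate_sbr(c(0, 0, 0, 2)), 0.5)
  x <- runif(7)
  expect_equal(aggregate_sbr(x), sum(x) / length(x))
  expect_error(aggregate_sbr(numeric()), "at least one")
})

test_that("metrics covary with pixel scale and are column-permutation invariant", {
  truth <- render_fspi_image(width_px = 120, height_px = 250, pixel_scale = 200,
                             interface = interface_law("sinusoid"),
                             n_luminophore_px = 900, seed = 10)
  base <- depth_metrics(truth$label_mask, truth$interface_row, truth$pixel_scale)
  doubled <- depth_metrics(truth$label_mask, truth$interface_row,
                           2 * truth$pixel_scale)
  for (col in c("L_mean", "L_median", "L_max", "SBR")) {
    expect_equal(doubled[[col]], 2 * base[[col]])
  }
  set.seed(11)
  perm <- sample(ncol(truth$label_mask))
  permuted <- depth_metrics(truth$label_mask[, perm], truth$interface_row[perm],
                            truth$pixel_scale)
  expect_equal(permuted$L_mean, base$L_mean)
  expect_equal(permuted$L_median, base$L_median)
})

test_that("a deeper pixel strictly raises L_max and weakly raises L_mean", {
  truth <- render_fspi_image(width_px = 80, height_px = 400, pixel_scale = 100,
                             interface_depth_cm = 1,
                             depth_law = depth_law("uniform", max_cm = 1),
                             n_luminophore_px = 200, seed = 12)
  base <- depth_metrics(truth$label_mask, truth$interface_row, 100)
  m2 <- truth$label_mask
  deep_row <- truth$interface_row[40] + 250  # 2.5 cm, below current max
  m2[deep_row, 40] <- 1L
  more <- depth_metrics(m2, truth$interface_row, 100)
  expect_gt(more$L_max, base$L_max)
  expect_gte(more$L_mean, base$L_mean)
})

test_that("reworking metrics are invariant to the order sides are merged in", {
  set.seed(13)
  sides <- lapply(1:4, function(i) {
    render_fspi_image(width_px = 60, height_px = 200, pixel_scale = 200,
                      n_luminophore_px = 150)$image
  })
  m1 <- analyze_profile(merge_sides(sides), 200)
  m2 <- analyze_profile(merge_sides(sides, side_order = c(3, 1, 4, 2)), 200)
  expect_equal(m1$L_mean, m2$L_mean)
  expect_equal(m1$L_median, m2$L_median)
  expect_equal(m1$L_max, m2$L_max)
})

test_that("full image analysis equals truth-mask analysis on noise-free bundles", {
  for (s in 1:3) {
    truth <- render_fspi_image(width_px = 180, height_px = 260, pixel_scale = 200,
                               interface = interface_law("sinusoid",
                                                         amplitude_cm = 0.2,
                                                         period_cm = 3),
                               n_luminophore_px = 1200, seed = 100 + s)
    # segmentation output vs truth mask, same (true) interface: exact
    seg <- segment_luminophores(truth$image)
    expect_equal(depth_metrics(seg, truth$interface_row, truth$pixel_scale),
                 truth_metrics(truth))
    # end-to-end with unsmoothed interface detection: exact on clean images
    est <- analyze_profile(truth$image, truth$pixel_scale, smoothing_window = 1)
    tm <- truth_metrics(truth)
    expect_equal(est$L_mean, tm$L_mean)
    expect_equal(est$L_median, tm$L_median)
    expect_equal(est$L_max, tm$L_max)
    expect_equal(est$SBR, tm$SBR)
  }
})
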